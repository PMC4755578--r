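#' Serialize network parameters to a directory
#'
#' Writes `W.csv` and `K.csv` (header-free, row-major, full double precision
#' via the C17 round-trip format) plus a `params.json` sidecar with the
#' scalar fields (tau, nonlinearity name, M, N). The round trip through
#' [read_network_params()] is bit-faithful at double precision.
#'
#' @param params A [network_params()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network_params <- function(params, dir) {
  stopifnot(inherits(params, "network_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(params$W, file.path(dir, "W.csv"))
  write_matrix_csv(params$K, file.path(dir, "K.csv"))
  jsonlite::write_json(
    list(tau = params$tau, nonlinearity = params$nl$name,
         M = params$M, N = params$N),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read network parameters from a directory
#'
#' @param dir Directory written by [write_network_params()].
#' @return A [network_params()] object. Only the logistic nonlinearity is
#'   currently deserializable.
#' @export
read_network_params <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$nonlinearity, "logistic"))
    stop("unknown nonlinearity in params.json: ", meta$nonlinearity)
  W <- read_matrix_csv(file.path(dir, "W.csv"))
  K <- read_matrix_csv(file.path(dir, "K.csv"))
  network_params(W, K, tau = as.numeric(meta$tau),
                 nl = logistic_nonlinearity())
}

# Full-precision header-free CSV (one row per matrix row, %.17g entries).
write_matrix_csv <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                          collapse = ","))
  writeLines(lines, path)
}

read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  m
}
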