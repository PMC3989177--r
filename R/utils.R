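#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Gyromagnetic ratio of 1H: 42.577 MHz/T = 42.577e3 cycles/(ms*T).
GAMMA_H <- 2 * pi * 42.5774785e3  # rad / (ms * T)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Run code with a temporarily seeded RNG
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers do not disturb the global stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

## Stable hash of an R object (provenance stamps); md5 of its serialization.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

## fftshift/ifftshift along every dimension of an array (DC at centre
## position floor(n/2)+1 in the shifted grid).
fftshift <- function(x) {
  d <- dim(x) %||% length(x)
  idx <- lapply(d, function(n) c((ceiling(n / 2) + 1):n, seq_len(ceiling(n / 2))))
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  if (is.null(dim(x))) dim(out) <- NULL
  out
}

ifftshift <- function(x) {
  d <- dim(x) %||% length(x)
  idx <- lapply(d, function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2))))
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  if (is.null(dim(x))) dim(out) <- NULL
  out
}
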