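#' Unit conversions between micrometers and meters
#'
#' All user-facing geometry is specified in micrometers (the natural scale
#' of trabecular microstructure); the solver works in SI meters. Conversion
#' happens exactly once at mesh-generation time.
#'
#' @param x numeric vector of lengths.
#' @return converted numeric vector.
#' @examples
#' m_to_um(um_to_m(1500)) # 1500
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname um_to_m
#' @export
m_to_um <- function(x) x * 1e6

# stop() with call. = FALSE everywhere: error messages name offending values
stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
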