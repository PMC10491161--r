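# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL means "use the current stream as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Half-open zeitgeber-time window
#'
#' Windows are half-open `[start, end)` so that ZT0-6 and ZT6-12 partition
#' the light phase without overlap.
#'
#' @param start_zt_hr,end_zt_hr window bounds in ZT hours,
#'   `0 <= start < end <= 24`.
#' @param label optional label; defaults to e.g. `"ZT6-12"`.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(start_zt_hr, end_zt_hr, label = NULL) {
  stopifnot(is.numeric(start_zt_hr), is.numeric(end_zt_hr))
  if (!(start_zt_hr >= 0 && start_zt_hr < end_zt_hr && end_zt_hr <= 24))
    stop("window must satisfy 0 <= start < end <= 24")
  structure(list(start = start_zt_hr, end = end_zt_hr,
                 label = label %||% sprintf("ZT%g-%g", start_zt_hr, end_zt_hr)),
            class = "window_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_window <- function(w) {
  if (inherits(w, "window_spec")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(window_spec(w[1], w[2]))
  stop("window must be a window_spec or a numeric pair c(start, end)")
}

# significance stars in figure-legend style
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
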