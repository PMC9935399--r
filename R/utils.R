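`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers (e.g.
#' [random_regions()]) do not perturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic child seed from a master seed and labels
#'
#' Stream-specific seeding: simulating one extra directory never perturbs the
#' tags of another. Plain 31-multiplier string hash modulo 2^31 - 1 (kept
#' below .Machine$integer.max so it is always a valid `set.seed()` input).
#'
#' @param seed master integer seed.
#' @param ... labels (assay, condition, replicate, ...) coerced to character.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  s <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
             collapse = "\r")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% m
  as.integer(h %% (m - 2) + 1)
}

## consistent number formatting for text output (byte-stable round trips)
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15)
      format(v, scientific = FALSE) else as.character(v)
  }, "")
  out
}

stop_if_not_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(x)
}
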