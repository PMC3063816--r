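# Internal helpers shared across the package.

#' Round half away from zero
#'
#' Reporting helper matching the conventional "half-up" rounding of printed
#' registry tables (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop without the call in the message; all user-facing errors go through this.
abort <- function(...) stop(..., call. = FALSE)

# Evaluate `expr` with a private RNG state seeded by `seed`, restoring the
# caller's state afterwards so library code never disturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Append a Total row to a per-class count table (reports mirror the printed
# tables, every one of which carries a Total row).
with_total <- function(df, sum_cols) {
  total <- df[1, , drop = FALSE]
  for (nm in names(df)) {
    total[[nm]] <- if (nm %in% sum_cols) sum(df[[nm]], na.rm = TRUE) else NA
  }
  total[[1]] <- "Total"
  df[[1]] <- as.character(df[[1]])
  rbind(df, total)
}
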