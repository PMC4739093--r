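# internal helpers shared across modules

# half-away-from-zero rounding; a tiny epsilon absorbs binary-representation
# error in products of decimal inputs (e.g. 0.089 * 329.616)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5 + 1e-9)
}

fgmc_round <- function(x, mode = c("half-away", "half-even")) {
  mode <- match.arg(mode)
  switch(mode,
    "half-away" = round_half_away(x),
    "half-even" = round(x)
  )
}

# "97,9 %" / "97.9%" -> 0.979 ; "0.979" -> 0.979 ; "" -> NA
parse_percent <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  pct <- grepl("%", x, fixed = TRUE)
  raw <- gsub("%", "", x, fixed = TRUE)
  raw <- gsub(",", ".", trimws(raw), fixed = TRUE)
  val <- suppressWarnings(as.numeric(raw))
  out[pct] <- val[pct] / 100
  out[!pct & nzchar(x)] <- val[!pct & nzchar(x)]
  out
}

fmt_percent <- function(x, digits = 1) {
  paste0(formatC(100 * x, format = "f", digits = digits), " %")
}

# country identity: trimmed, case-folded
norm_country <- function(x) tolower(trimws(x))

# run code under a seed without disturbing the caller's RNG state
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# calendar-date shift by whole years with Feb-29 rollback to Feb-28
add_years <- function(date, n) {
  lubridate::`%m+%`(date, lubridate::years(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fgmc <- function(...) stop(..., call. = FALSE)
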