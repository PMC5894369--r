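#' Five-year age bands used by the cohort model
#'
#' The model resolves smokers into 5-year age bands spanning ages 15 to 90,
#' the range over which the cessation benefit schedule is defined. Band labels
#' are of the form `"15-19"`, ..., `"85-89"`.
#'
#' @return A tibble with columns `age_band` (label), `lower`, `upper`
#'   (integer band limits, upper exclusive) and `mid` (band midpoint in years).
#' @export
#' @examples
#' age_bands()
age_bands <- function() {
  lower <- seq(15L, 85L, by = 5L)
  tibble(
    age_band = sprintf("%d-%d", lower, lower + 4L),
    lower = lower,
    upper = lower + 5L,
    mid = lower + 2.5
  )
}

# Stable, platform-independent child seed for one country: a polynomial hash
# of the name folded into the top-level seed, kept below 2^31 so it is a valid
# R integer seed. Gives reproducible per-country streams independent of the
# order in which countries are processed.
country_seed <- function(seed, country) {
  h <- 0
  for (cp in utf8ToInt(country)) h <- (h * 31 + cp) %% 1000000007
  as.integer((abs(seed) + h) %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Path to a packaged input file
#'
#' Convenience accessor for the CSV fixtures shipped with the package
#' (country indicators, smokers by quintile, the published outcome table used
#' by replay mode, and the synthetic disease-cost and elasticity defaults).
#'
#' @param file File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' smoketax_file()
#' smoketax_file("countries.csv")
smoketax_file <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "smoketax")))
  }
  path <- system.file("extdata", file, package = "smoketax", mustWork = FALSE)
  if (!nzchar(path)) {
    abort(sprintf("no packaged file '%s'; see smoketax_file() for choices", file))
  }
  path
}

# Parse a numeric column that may contain censored cells like "<0.1".
# Censored cells are replaced by the midpoint of [0, bound] and flagged.
parse_censored <- function(x) {
  x_chr <- trimws(as.character(x))
  censored <- grepl("^<", x_chr)
  out <- suppressWarnings(as.numeric(sub("^<", "", x_chr)))
  out[censored] <- out[censored] / 2
  if (anyNA(out) & any(!is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))
    abort(sprintf("cannot parse numeric cell(s): %s",
                  paste(unique(x_chr[bad]), collapse = ", ")))
  }
  attr(out, "censored") <- censored
  out
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("schema error in %s: missing column(s) %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
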