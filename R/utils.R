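DNA_BASES <- c("A", "C", "G", "T")

# deterministic sub-seed per named artifact, so regenerating one artifact
# never perturbs another; kept below 2^31 for set.seed()
substream_seed <- function(seed, tag) {
  h <- 0
  for (x in utf8ToInt(tag)) h <- (h * 31 + x) %% 2147483647
  as.integer((seed %% 2147483647) * 7919 %% 2147483647 + h) %% 2147483647L
}

with_substream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, tag))
  force(expr)
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be in %s%s, %s%s; got %s",
                  name, if (lo_open) "(" else "[", format(lo),
                  format(hi), if (hi_open) ")" else "]",
                  paste(format(x), collapse = ",")))
  }
  invisible(x)
}

# reverse complement for plain character strings
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# exact product of small positive integers as a decimal string
# (diversity products overflow 32-bit integers and, in general, doubles)
exact_product <- function(counts) {
  stopifnot(all(counts == floor(counts)), all(counts >= 1))
  digits <- c(1L) # little-endian base 1e4
  for (k in counts) {
    carry <- 0
    digits <- as.integer(digits) * as.integer(k)
    for (i in seq_along(digits)) {
      v <- digits[i] + carry
      digits[i] <- v %% 10000L
      carry <- v %/% 10000L
    }
    while (carry > 0) {
      digits <- c(digits, carry %% 10000L)
      carry <- carry %/% 10000L
    }
  }
  n <- length(digits)
  parts <- c(format(digits[n]),
             if (n > 1) sprintf("%04d", rev(digits[-n])))
  paste(parts, collapse = "")
}

# "~1.97 x 10^14"-style rendering of a decimal integer string, 3 sig. digits
render_scientific <- function(s) {
  stopifnot(grepl("^[0-9]+$", s))
  exp <- nchar(s) - 1L
  if (exp < 3) return(s)
  mant <- as.numeric(paste0(substr(s, 1, 1), ".", substr(s, 2, min(6, nchar(s)))))
  mant <- round(mant, 2)
  if (mant >= 10) {
    mant <- mant / 10
    exp <- exp + 1L
  }
  sprintf("~%.2f × 10^%d", mant, exp)
}

log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(...)))
}
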