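# Run `code` under a fixed RNG seed without clobbering the caller's RNG
# stream.  A NULL seed leaves the global stream untouched.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# Extract the n x 3 T-score matrix from a length-3 numeric vector, a 3-column
# matrix, or a data frame carrying the canonical T-score columns.
tscore_matrix <- function(t) {
  if (is.data.frame(t)) {
    missing <- setdiff(TSCORE_COLS, names(t))
    if (length(missing) > 0) {
      abort(sprintf("Missing T-score column(s): %s.",
                    paste(missing, collapse = ", ")))
    }
    m <- as.matrix(t[TSCORE_COLS])
  } else if (is.matrix(t)) {
    if (ncol(t) != 3L) abort("A T-score matrix must have 3 columns.")
    m <- t
  } else if (is.numeric(t)) {
    if (length(t) != 3L) {
      abort("A single T-score vector must have exactly 3 components (L1-L4 spine, femoral neck, total hip).")
    }
    m <- matrix(t, nrow = 1L)
  } else {
    abort("`t` must be a numeric vector of length 3, a 3-column matrix, or a cohort data frame.")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    abort("T-scores must be finite and non-missing at all three sites.")
  }
  colnames(m) <- TSCORE_COLS
  m
}
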