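# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Restores the caller's `.Random.seed` afterwards so that generators and
#' model fits are reproducible without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stop_salnet <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "salnet_error")))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_salnet(name, " must be TRUE or FALSE", class = "salnet_value_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_salnet(name, " must be an integer >= ", min, class = "salnet_value_error")
  }
  invisible(as.integer(x))
}

assert_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    stop_salnet(name, " must be a finite number ", if (strict) "> " else ">= ",
                min, class = "salnet_value_error")
  }
  invisible(as.numeric(x))
}

# mirror a volume about the mid-sagittal plane (axis 1 = sagittal,
# index 1 = rightmost slice)
flip_sagittal <- function(a) {
  a[dim(a)[1]:1, , , drop = FALSE]
}

# rank-based AUC of `score` for separating labels (1 over 0)
rank_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))[seq_along(pos)]
  (sum(r) - length(pos) * (length(pos) + 1) / 2) / (length(pos) * length(neg))
}
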