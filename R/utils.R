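# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state so package functions never perturb the
#' user's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage sub-seed so pipeline stages can be regenerated
# independently from one top-level seed. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offs <- c(panel = 11L, expression = 23L, sumstats = 37L, gsea = 53L,
            permutation = 71L, pipeline = 89L)
  off <- offs[[stage]]
  as.integer((as.numeric(seed) * 1103L + off) %% 2147483647)
}

stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "glucoMR_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stopf("glucoMR_parameter_error", "`%s` must be a single value in (0, 1), got %s",
          name, paste(format(x), collapse = ","))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stopf("glucoMR_parameter_error", "`%s` must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

# message-based logging with a package-level threshold
.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"

log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set package log level
#' @param level one of "debug", "info", "warn", "quiet"
#' @return previous level, invisibly
#' @export
glucomr_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  prev <- .log_env$level
  .log_env$level <- level
  invisible(prev)
}

log_msg <- function(level, fmt, ...) {
  if (log_levels[[level]] >= log_levels[[.log_env$level]]) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Benjamini-Hochberg adjusted p-values
#' @noRd
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Two-proportion z-test from counts; alternative in c("two.sided","greater").
two_prop_z <- function(x1, n1, x2, n2, alternative = "two.sided") {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater   = stats::pnorm(z, lower.tail = FALSE),
              stop("unknown alternative"))
  list(z = z, p = p, prop1 = p1, prop2 = p2)
}

# Satterthwaite (matched-moments) upper-tail p for a weighted sum of
# independent 1-df chi-squares with weights `lambda`.
satterthwaite_p <- function(stat, lambda) {
  lambda <- lambda[lambda > .Machine$double.eps]
  if (length(lambda) == 0L) return(1)
  s1 <- sum(lambda)
  s2 <- sum(lambda^2)
  scale <- s2 / s1
  df <- s1^2 / s2
  stats::pchisq(stat / scale, df = df, lower.tail = FALSE)
}
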