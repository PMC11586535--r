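#' Reduced murmur grade levels
#'
#' The five-level reduced murmur intensity scale used throughout the package:
#' absence of a murmur plus the four-level collapse of the Levine I-VI scale.
#' The order is clinically meaningful (none < soft < moderate < loud <
#' thrilling).
#'
#' @return Character vector of the five grade labels, in ascending order.
#' @export
grade_levels <- function() {
  c("none", "soft", "moderate", "loud", "thrilling")
}

#' Auscultation site labels
#'
#' @return Character vector of the three recording sites.
#' @export
site_levels <- function() {
  c("left_apex", "left_base", "right_side")
}

# Coerce to an ordered grade factor; errors on unknown labels.
as_grade <- function(x) {
  if (is.numeric(x)) {
    stopifnot(all(x >= 0 & x <= 4))
    x <- grade_levels()[x + 1L]
  }
  bad <- setdiff(unique(as.character(x)), grade_levels())
  if (length(bad) > 0) {
    stop("unknown murmur grade label(s): ", paste(bad, collapse = ", "))
  }
  factor(as.character(x), levels = grade_levels(), ordered = TRUE)
}

# 0-based ordinal index of a grade (none = 0 ... thrilling = 4)
grade_index <- function(x) as.integer(as_grade(x)) - 1L

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a string hash folded into [0, 2^31 - 1]; used to derive per-stage and
# per-patient seeds from a single user seed without consuming the global RNG.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

#' Derive a stage-specific seed from a global seed
#'
#' All randomness in multi-stage workflows flows from one user-supplied seed;
#' each stage (and each repeat within a stage) receives its own deterministic
#' sub-seed via string hashing so that stages are statistically independent
#' yet exactly reproducible.
#'
#' @param seed Integer global seed.
#' @param ... Character or integer tags naming the stage (and repeat index).
#' @return A single integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  fnv1a(paste(c(seed, ...), collapse = "/"))
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Sample one level from a named probability vector.
sample_level <- function(probs) {
  sample(names(probs), 1L, prob = probs)
}

check_probs <- function(p, what) {
  if (abs(sum(p) - 1) > 1e-6) {
    stop("marginal distribution for ", what, " does not sum to 1 (sum = ",
         format(sum(p)), ")")
  }
  if (any(p < 0)) stop("negative probability in marginal for ", what)
  invisible(TRUE)
}

# log-normal parameterized by printed median and interquartile range
rlnorm_median_iqr <- function(n, median, q1, q3) {
  sdlog <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}
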