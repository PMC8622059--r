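#' Assessment sets
#'
#' The ordered fuzzy assessment levels with one anchor value per level on
#' the normalized [0, 1] scale. The default is the 4-level land ecological
#' security set V = (S, RS, RU, U) - safe, relatively safe, relatively
#' unsafe, unsafe - with equally spaced anchors (1.0, 0.75, 0.5, 0.25).
#' Anchors double as the default level scores used to collapse a membership
#' vector to a scalar; both are configuration, not constants, because
#' published studies rarely disclose the Delphi-elicited values they used.
#'
#' @param levels Character vector of level labels, ordered to match
#'   `anchors`.
#' @param anchors Strictly monotone anchor values in [0, 1]. Higher anchor
#'   means safer under the default orientation.
#' @param level_scores Scores used for scalar collapse; default the anchors.
#' @return A list of class `assessment_set`.
#' @export
assessment_set <- function(levels = c("S", "RS", "RU", "U"),
                           anchors = c(1.0, 0.75, 0.5, 0.25),
                           level_scores = anchors) {
  if (length(levels) != length(anchors) || length(levels) < 2L) {
    les_stop_schema("need one anchor per level and at least two levels")
  }
  d <- diff(anchors)
  if (anyNA(anchors) || !(all(d > 0) || all(d < 0))) {
    les_stop_value("anchors must be strictly monotone")
  }
  if (length(level_scores) != length(levels)) {
    les_stop_schema("level_scores must match the number of levels")
  }
  structure(list(levels = as.character(levels), anchors = as.numeric(anchors),
                 level_scores = as.numeric(level_scores)),
            class = "assessment_set")
}

#' Triangular membership of a normalized value
#'
#' Maps a normalized value x to a degree of membership in each assessment
#' level via triangular membership functions: for a level with anchor r_i
#' and neighboring anchors (r_min, r_max), membership rises linearly as
#' `(x - r_min) / (r_i - r_min)` on (r_min, r_i], falls as
#' `(r_max - x) / (r_max - r_i)` on (r_i, r_max), and is 0 outside.
#' The terminal levels use half-triangles clamped at the scale ends, so
#' membership stays 1 at and beyond the terminal anchor (x = 1 is fully
#' "S" under the default orientation). The vector is renormalized to sum 1.
#'
#' @param x A normalized value in [0, 1].
#' @param set An [assessment_set()].
#' @return Named membership vector over `set$levels`, summing to 1.
#' @export
#' @examples
#' triangular_membership(0.625, assessment_set())  # 0.5 RS / 0.5 RU
triangular_membership <- function(x, set = assessment_set()) {
  if (length(x) != 1L || is.na(x) || x < -1e-12 || x > 1 + 1e-12) {
    les_stop_value(sprintf("x must be a single value in [0, 1] (got %s)",
                           format(x)))
  }
  x <- min(max(x, 0), 1)
  ord <- order(set$anchors)
  r <- set$anchors[ord]
  m <- length(r)
  mu <- numeric(m)
  for (i in seq_len(m)) {
    lo <- if (i == 1L) -Inf else r[i - 1L]
    hi <- if (i == m) Inf else r[i + 1L]
    mu[i] <- if (x <= r[i]) {
      if (i == 1L) 1 else if (x <= lo) 0 else (x - lo) / (r[i] - lo)
    } else {
      if (i == m) 1 else if (x >= hi) 0 else (hi - x) / (hi - r[i])
    }
  }
  mu <- mu / sum(mu)
  out <- numeric(m)
  out[ord] <- mu
  stats::setNames(out, set$levels)
}

#' Single-factor membership matrix
#'
#' Row i is the triangular membership vector of factor i's normalized
#' value: an n x m row-stochastic matrix (each row sums to 1).
#'
#' @param values Named numeric vector of normalized values in [0, 1].
#' @param set An [assessment_set()].
#' @return Matrix with one row per factor, one column per level.
#' @export
build_membership_matrix <- function(values, set = assessment_set()) {
  rows <- lapply(seq_along(values), function(i) {
    tryCatch(triangular_membership(values[[i]], set),
             les_error = function(e) {
               id <- if (!is.null(names(values))) names(values)[i] else i
               les_stop(sprintf("factor %s: %s", id, conditionMessage(e)),
                        class(e)[1L], factor = id)
             })
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(values)
  colnames(mat) <- set$levels
  mat
}

#' Membership rows from expert votes
#'
#' The Delphi-elicitation route: a matrix of non-negative vote counts
#' (factors x levels) is converted to row proportions
#' `r[i, j] = V[i, j] / sum_j V[i, j]`.
#'
#' @param votes Non-negative numeric matrix with positive row sums.
#' @return A row-stochastic membership matrix.
#' @export
membership_from_votes <- function(votes) {
  votes <- as.matrix(votes)
  if (anyNA(votes) || any(votes < 0)) {
    les_stop_value("votes must be non-negative and non-missing")
  }
  rs <- rowSums(votes)
  if (any(rs == 0)) les_stop_value("every factor needs at least one vote")
  sweep(votes, 1L, rs, "/")
}

#' Weighted-average fuzzy synthesis
#'
#' Combines the single-factor membership matrix R with the factor weights W
#' using the weighted-average operator M(*, +): `X = W %*% R`, an ordinary
#' matrix-vector product (not max-min composition). Because W sums to 1 and
#' every row of R sums to 1, X is again a membership vector. The scalar
#' score is `sum(X * level_scores)` and the level follows [classify()].
#'
#' @param weights A [weight_vector()] over the factors (labels must match
#'   `rownames(matrix)` when both are present).
#' @param matrix Membership matrix from [build_membership_matrix()] or
#'   [membership_from_votes()].
#' @param set An [assessment_set()].
#' @return A list of class `fuzzy_result`: `membership`, `scalar_score`,
#'   `level`.
#' @export
synthesize <- function(weights, matrix, set = assessment_set()) {
  if (length(weights) != nrow(matrix)) {
    les_stop_schema("one weight per matrix row is required")
  }
  if (!is.null(rownames(matrix)) && !is.null(names(weights)) &&
      !identical(names(weights), rownames(matrix))) {
    les_stop_schema("weight labels do not match membership matrix rows")
  }
  x <- drop(as.numeric(weights) %*% matrix)
  names(x) <- set$levels
  structure(list(membership = x,
                 scalar_score = sum(x * set$level_scores),
                 level = classify(x, set)),
            class = "fuzzy_result")
}

#' Maximum-membership classification
#'
#' Assigns the level with the largest membership; ties are broken toward
#' the less safe level (the one with the lower anchor), a conservative
#' convention for a security assessment.
#'
#' @param membership Non-negative membership vector over `set$levels`.
#' @param set An [assessment_set()].
#' @return A level label.
#' @export
classify <- function(membership, set = assessment_set()) {
  if (length(membership) != length(set$levels)) {
    les_stop_schema("membership length must match the number of levels")
  }
  if (anyNA(membership) || any(membership < 0) || all(membership == 0)) {
    les_stop_value("membership must be non-negative with positive total")
  }
  top <- which(membership >= max(membership) - 1e-12)
  set$levels[top[which.min(set$anchors[top])]]
}
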