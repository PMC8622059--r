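#' Weight vectors
#'
#' A named vector of non-negative criterion weights summing to 1.
#'
#' @param weights Numeric vector, non-negative.
#' @param labels Optional criterion ids (defaults to `names(weights)`).
#' @param tol Tolerance on the sum-to-1 check.
#' @return A named numeric vector of class `weight_vector`.
#' @export
weight_vector <- function(weights, labels = names(weights), tol = 1e-9) {
  force(labels)
  weights <- as.numeric(weights)
  if (length(weights) == 0L || anyNA(weights)) {
    les_stop_value("weights must be non-empty and non-missing")
  }
  if (any(weights < 0)) les_stop_value("weights must be non-negative")
  if (abs(sum(weights) - 1) > tol) {
    les_stop_value(sprintf("weights must sum to 1 (got %.6f)", sum(weights)))
  }
  if (is.null(labels)) labels <- paste0("w", seq_along(weights))
  if (length(labels) != length(weights) || anyDuplicated(labels)) {
    les_stop_schema("labels must be unique and match the weight length")
  }
  structure(stats::setNames(weights, labels), class = "weight_vector")
}

#' Pairwise judgment matrices
#'
#' A positive reciprocal matrix of pairwise importance ratios: unit
#' diagonal, `a[j, i] = 1 / a[i, j]`. Entries elicited on the Saaty 1-9
#' scale lie in [1/9, 9]; entries outside that range (possible for
#' synthetic perturbed matrices) trigger a warning, not an error.
#'
#' @param entries Square numeric matrix of positive entries.
#' @param labels Criterion ids (defaults to `colnames(entries)`).
#' @param reciprocity_tol Tolerance on the reciprocity check.
#' @return A matrix of class `judgment_matrix`.
#' @export
judgment_matrix <- function(entries, labels = colnames(entries),
                            reciprocity_tol = 1e-9) {
  entries <- as.matrix(entries)
  n <- nrow(entries)
  if (n != ncol(entries)) les_stop_schema("judgment matrix must be square")
  if (anyNA(entries) || any(entries <= 0)) {
    les_stop_value("judgment matrix entries must be positive and non-missing")
  }
  if (any(abs(diag(entries) - 1) > reciprocity_tol)) {
    les_stop_value("judgment matrix diagonal must be 1")
  }
  if (any(abs(entries * t(entries) - 1) > reciprocity_tol)) {
    les_stop_value("judgment matrix must be reciprocal: a[j,i] = 1/a[i,j]")
  }
  if (any(entries > 9 + 1e-9) || any(entries < 1 / 9 - 1e-12)) {
    warning("judgment matrix has entries outside the Saaty [1/9, 9] scale",
            call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("C", seq_len(n))
  dimnames(entries) <- list(labels, labels)
  class(entries) <- c("judgment_matrix", class(entries))
  entries
}

#' Build a judgment matrix from known weights
#'
#' Constructs `a[i, j] = (w[i] / w[j]) * exp(eps[i, j])` with antisymmetric
#' log-scale noise `eps` of standard deviation `perturbation`; reciprocity
#' holds exactly by construction. With `perturbation = 0` the matrix is
#' perfectly consistent (CR = 0) and its principal eigenvector recovers the
#' weights, which makes this the ground-truth generator for weight-recovery
#' experiments and for reconstructing consistent matrices from published
#' weight tables.
#'
#' @param weights A [weight_vector()] (all entries strictly positive).
#' @param perturbation Non-negative log-scale noise sd.
#' @param seed Seed used when `perturbation > 0`.
#' @return A [judgment_matrix()].
#' @export
#' @examples
#' m <- judgment_from_weights(weight_vector(c(S1 = 0.3341, S2 = 0.3780,
#'                                            S3 = 0.2879)))
#' consistency(m)$cr   # 0
judgment_from_weights <- function(weights, perturbation = 0, seed = 1L) {
  if (any(weights <= 0)) {
    les_stop_value("weight ratios are undefined for zero weights")
  }
  if (perturbation < 0) les_stop_value("perturbation must be >= 0")
  n <- length(weights)
  a <- outer(as.numeric(weights), as.numeric(weights), "/")
  if (perturbation > 0) {
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- with_seed(seed,
      stats::rnorm(n * (n - 1) / 2, sd = perturbation))
    eps <- eps - t(eps)
    a <- a * exp(eps)
  }
  # enforce exact unit diagonal / reciprocity against floating-point drift
  diag(a) <- 1
  a[lower.tri(a)] <- t(1 / a)[lower.tri(a)]
  suppressWarnings(judgment_matrix(a, labels = names(weights)))
}

#' Principal-eigenvector weights of a judgment matrix
#'
#' The default extractor is power iteration started from the uniform vector,
#' normalizing to sum 1 each step; `lambda_max` is taken as the mean of the
#' componentwise Rayleigh ratios at convergence. `method = "geometric"`
#' gives the geometric-mean-of-rows approximation instead (exact for
#' consistent matrices).
#'
#' @param m A [judgment_matrix()].
#' @param tol Convergence tolerance on the weight vector (sup norm).
#' @param max_iter Iteration cap; exceeding it raises a numeric error
#'   carrying the residual.
#' @param method `"power"` or `"geometric"`.
#' @return A list with `weights` (a [weight_vector()]) and `lambda_max`.
#' @export
principal_eigen <- function(m, tol = 1e-12, max_iter = 10000L,
                            method = c("power", "geometric")) {
  method <- match.arg(method)
  n <- nrow(m)
  a <- unclass(m)
  if (method == "geometric") {
    w <- apply(a, 1L, function(r) exp(mean(log(r))))
    w <- w / sum(w)
  } else {
    w <- rep(1 / n, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w_new <- drop(a %*% w)
      w_new <- w_new / sum(w_new)
      if (max(abs(w_new - w)) < tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged) {
      les_stop_numeric(sprintf(
        "power iteration did not converge in %d iterations (residual %.3e)",
        max_iter, max(abs(drop(a %*% w) / sum(a %*% w) - w))))
    }
  }
  lambda_max <- mean(drop(a %*% w) / w)
  list(weights = weight_vector(w, labels = rownames(m)),
       lambda_max = lambda_max)
}

# Saaty random index for matrix orders 1..10
RI_TABLE <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' @rdname consistency
#' @export
random_index <- function(n, ri_table = RI_TABLE) {
  if (n < 1 || n > length(ri_table)) {
    les_stop_value(sprintf(
      "random index only defined for orders 1..%d (got %d); supply ri_table",
      length(ri_table), n))
  }
  ri_table[n]
}

#' Consistency of a judgment matrix
#'
#' Computes the principal eigenvalue `lambda_max`, the consistency index
#' `CI = (lambda_max - n) / (n - 1)`, the random index `RI(n)` (Saaty's
#' table for orders up to 10), and the consistency ratio `CR = CI / RI`.
#' Matrices of order 2 or less are always consistent (`CI = CR = 0`). A
#' matrix is flagged consistent when `CR < threshold` (conventionally 0.1).
#'
#' @param m A [judgment_matrix()].
#' @param threshold CR acceptance threshold.
#' @param ri_table Random-index table indexed by matrix order, extendable
#'   beyond order 10 if needed.
#' @param n Matrix order (for `random_index`).
#' @return A list of class `consistency_report` with elements `n`,
#'   `lambda_max`, `ci`, `ri`, `cr`, `consistent`.
#' @export
consistency <- function(m, threshold = 0.1, ri_table = RI_TABLE) {
  n <- nrow(m)
  lambda_max <- principal_eigen(m)$lambda_max
  if (n <= 2L) {
    ci <- 0
    cr <- 0
    ri <- random_index(n, ri_table)
  } else {
    ci <- (lambda_max - n) / (n - 1)
    ri <- random_index(n, ri_table)
    cr <- ci / ri
  }
  structure(list(n = n, lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
                 consistent = n <= 2L || cr < threshold),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency_report> n=%d lambda_max=%.6f CI=%.6f RI=%.2f CR=%.6f [%s]\n",
    x$n, x$lambda_max, x$ci, x$ri, x$cr,
    if (x$consistent) "consistent" else "INCONSISTENT"))
  invisible(x)
}

#' Hierarchical AHP weight aggregation
#'
#' Derives main-factor weights from the top-level judgment matrix and local
#' (within-group) weights from each group matrix, then composes them: the
#' global weight of sub-factor j in group g is
#' `mainWeight(g) * localWeight(j | g)`, so the global weights sum to 1.
#' Every matrix must pass the CR < 0.1 consistency test unless
#' `force = TRUE`.
#'
#' @param top [judgment_matrix()] over the group ids.
#' @param groups Named list of [judgment_matrix()], one per group id in
#'   `top`, labelled by the group's sub-factor ids.
#' @param force Skip the consistency gate.
#' @param method Eigenvector extraction method, see [principal_eigen()].
#' @return A list with `main` and `global` [weight_vector()]s and the
#'   per-matrix `reports`.
#' @export
hierarchical_weights <- function(top, groups, force = FALSE,
                                 method = c("power", "geometric")) {
  method <- match.arg(method)
  if (!setequal(rownames(top), names(groups))) {
    les_stop_schema("group matrix names must match the top-level criteria")
  }
  check <- function(m, label) {
    rep <- consistency(m)
    if (!rep$consistent && !force) {
      les_stop_consistency(sprintf(
        "judgment matrix '%s' fails the consistency test (CR = %.4f >= 0.1)",
        label, rep$cr), report = rep)
    }
    rep
  }
  reports <- c(list(top = check(top, "top")),
               lapply(stats::setNames(nm = names(groups)),
                      function(g) check(groups[[g]], g)))
  main <- principal_eigen(top, method = method)$weights
  global <- unlist(lapply(rownames(top), function(g) {
    local <- principal_eigen(groups[[g]], method = method)$weights
    main[[g]] * as.numeric(local)
  }))
  labels <- unlist(lapply(rownames(top), function(g) rownames(groups[[g]])))
  list(main = main,
       global = weight_vector(global, labels = labels),
       reports = reports)
}

#' Read / write judgment matrices
#'
#' CSV layout: a header row of criterion ids followed by the n x n entries.
#' JSON layout: `{"labels": [...], "rows": [[...], ...]}`. With
#' `auto_complete = TRUE` an upper-triangular elicitation (lower triangle
#' empty/NA) is completed by reciprocity.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param auto_complete Fill the lower triangle as `1 / a[i, j]`.
#' @param m A [judgment_matrix()] (for `write_judgment`).
#' @return A [judgment_matrix()].
#' @export
read_judgment <- function(path, auto_complete = FALSE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    entries <- matrix(unlist(obj$rows), nrow = length(obj$labels),
                      byrow = TRUE)
    labels <- obj$labels
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    entries <- as.matrix(df)
    labels <- colnames(df)
  }
  if (auto_complete) {
    diag(entries) <- 1
    low <- lower.tri(entries)
    entries[low] <- t(1 / entries)[low]
  }
  judgment_matrix(entries, labels = labels)
}

#' @rdname read_judgment
#' @export
write_judgment <- function(m, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(labels = rownames(m),
                              rows = apply(unclass(m), 1L, identity,
                                           simplify = FALSE)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(unclass(m), check.names = FALSE), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
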