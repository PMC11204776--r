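#' Classifier back ends
#'
#' The four supervised methods compared in the pipeline, behind one
#' interface: `"lr"` (L2-penalized multinomial logistic regression, via
#' glmnet with a small fixed lambda), `"svm"` (linear soft-margin support
#' vector machine, one-vs-one, each binary dual solved exactly as a
#' quadratic program), `"dt"` (CART decision tree, Gini impurity, grown to
#' purity), and `"rf"` (random forest: 100 bagged CART trees, each on a
#' bootstrap sample and a random feature subspace of size ~sqrt(p)).
#' All fits are deterministic given `seed`; ties in votes and leaf
#' majorities break toward the lexicographically smallest label.
#'
#' @name classifiers
NULL

#' Fit a classifier
#'
#' @param x Numeric matrix (rows = cases, columns = features).
#' @param y Label vector (coerced to character).
#' @param method One of `"lr"`, `"svm"`, `"dt"`, `"rf"`.
#' @param seed Integer seed (used by `"rf"` bootstraps; other methods are
#'   deterministic).
#' @param cost SVM soft-margin cost C (default 1, the customary libsvm default).
#' @param lambda Ridge penalty for `"lr"` (default 1e-3).
#' @param n_trees Forest size (default 100).
#' @return A list of class `psm_model`.
#' @export
fit_classifier <- function(x, y, method = c("svm", "dt", "rf", "lr"),
                           seed = 1, cost = 1, lambda = 1e-3,
                           n_trees = 100) {
  method <- match.arg(method)
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  if (nrow(x) < 1) stop("empty training set")
  lev <- sort(unique(y))
  if (length(lev) == 1) {
    return(structure(list(method = "constant", levels = lev,
                          constant = lev[1]), class = "psm_model"))
  }
  fit <- switch(method,
    lr = fit_lr(x, y, lev, lambda),
    svm = fit_svm_ovo(x, y, lev, cost),
    dt = fit_cart(x, y, lev),
    rf = fit_forest(x, y, lev, seed, n_trees))
  structure(list(method = method, levels = lev, fit = fit),
            class = "psm_model")
}

#' Predict labels from a fitted classifier
#' @param model A `psm_model` from [fit_classifier()].
#' @param newx Numeric matrix of cases to classify.
#' @return Character vector of predicted labels.
#' @export
predict_classifier <- function(model, newx) {
  stopifnot(inherits(model, "psm_model"))
  newx <- as.matrix(newx); storage.mode(newx) <- "double"
  if (model$method == "constant")
    return(rep(model$constant, nrow(newx)))
  switch(model$method,
    lr = predict_lr(model$fit, newx, model$levels),
    svm = predict_svm_ovo(model$fit, newx, model$levels),
    dt = predict_cart(model$fit, newx),
    rf = predict_forest(model$fit, newx, model$levels))
}

## --- logistic regression (glmnet ridge, multinomial) ---------------------

fit_lr <- function(x, y, lev, lambda) {
  # glmnet needs >= 2 columns; pad a zero column for univariate problems
  pad <- ncol(x) < 2
  if (pad) x <- cbind(x, 0)
  # glmnet warns about class counts < 8; small clinical strata are the
  # normal operating regime here, so that warning is muffled
  fit <- withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = lev),
                   family = if (length(lev) == 2) "binomial"
                            else "multinomial",
                   alpha = 0, lambda = lambda, standardize = TRUE),
    warning = function(w) {
      if (grepl("fewer than 8|dangerous ground", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(fit = fit, lambda = lambda, pad = pad)
}

predict_lr <- function(f, newx, lev) {
  if (f$pad) newx <- cbind(newx, 0)
  as.character(stats::predict(f$fit, newx, s = f$lambda, type = "class"))
}

## --- linear SVM (exact dual QP per one-vs-one pair) ----------------------

# Binary soft-margin linear SVM on standardized features.
# Dual: max sum(a) - a' Q a / 2, 0 <= a <= C, sum(a * y) = 0,
# Q = (y y') * (X X'). Solved with quadprog (D regularized for PD).
svm_binary <- function(x, ysign, cost) {
  n <- nrow(x)
  K <- tcrossprod(x)
  Q <- (ysign %o% ysign) * K
  D <- Q + diag(1e-8 * max(1, diag(Q)), n)
  A <- cbind(ysign, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  a <- pmin(cost, pmax(0, sol$solution))
  w <- colSums(a * ysign * x)
  on_margin <- a > 1e-6 * cost & a < cost * (1 - 1e-6)
  b <- if (any(on_margin)) {
    mean(ysign[on_margin] - x[on_margin, , drop = FALSE] %*% w)
  } else {
    sv <- a > 1e-6 * cost
    f <- x[sv, , drop = FALSE] %*% w
    -(max(f[ysign[sv] == -1], -Inf) + min(f[ysign[sv] == 1], Inf)) / 2
  }
  list(w = w, b = as.numeric(b))
}

fit_svm_ovo <- function(x, y, lev, cost) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd); sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- scale(x, mu, sdv)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    ysign <- ifelse(y[sel] == pr[2], 1, -1)  # pr[1] -> -1, pr[2] -> +1
    m <- svm_binary(xs[sel, , drop = FALSE], ysign, cost)
    c(m, list(neg = pr[1], pos = pr[2]))
  })
  list(machines = machines, mu = mu, sdv = sdv)
}

predict_svm_ovo <- function(f, newx, lev) {
  xs <- scale(newx, f$mu, f$sdv)
  votes <- matrix(0L, nrow(newx), length(lev), dimnames = list(NULL, lev))
  for (m in f$machines) {
    d <- as.numeric(xs %*% m$w + m$b)
    winner <- ifelse(d >= 0, m$pos, m$neg)
    for (i in seq_along(winner))
      votes[i, winner[i]] <- votes[i, winner[i]] + 1L
  }
  lev[apply(votes, 1, which.max)]  # which.max ties -> first (lowest label)
}

## --- CART decision tree (Gini) -------------------------------------------

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

majority_label <- function(y, lev) {
  tab <- table(factor(y, levels = lev))
  lev[which.max(tab)]  # ties -> lowest label
}

# Recursive CART growth; feats restricts candidate split features (forest
# subspaces). Deterministic: best split by (impurity, feature index,
# threshold) lexicographic order. The per-feature search is vectorized:
# sort once, accumulate class counts, and score every cut point at once.
grow_cart <- function(x, y, lev, depth, max_depth, min_split, feats) {
  n <- length(y)
  if (n < min_split || depth >= max_depth || length(unique(y)) == 1) {
    return(list(leaf = TRUE, label = majority_label(y, lev)))
  }
  yi <- match(y, lev)
  parent_imp <- 1 - sum((tabulate(yi, length(lev)) / n)^2)
  best <- NULL
  for (j in feats) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]
    cuttable <- which(vs[-n] < vs[-1])  # cut after position i
    if (length(cuttable) == 0) next
    cum <- vapply(seq_along(lev), function(l) cumsum(yi[ord] == l),
                  numeric(n))
    tot <- cum[n, ]
    nl <- cuttable
    nr <- n - nl
    gl <- 1 - rowSums((cum[cuttable, , drop = FALSE] / nl)^2)
    gr <- 1 - rowSums((sweep(cum[cuttable, , drop = FALSE], 2, tot,
                             function(a, b) b - a) / nr)^2)
    imp <- (nl * gl + nr * gr) / n
    i_best <- which.min(imp)
    if (is.null(best) || imp[i_best] < best$imp - 1e-12) {
      pos <- cuttable[i_best]
      best <- list(imp = imp[i_best], j = j,
                   t = (vs[pos] + vs[pos + 1]) / 2)
    }
  }
  if (is.null(best) || best$imp >= parent_imp - 1e-12) {
    return(list(leaf = TRUE, label = majority_label(y, lev)))
  }
  left <- x[, best$j] <= best$t
  list(leaf = FALSE, feature = best$j, threshold = best$t,
       left = grow_cart(x[left, , drop = FALSE], y[left], lev,
                        depth + 1, max_depth, min_split, feats),
       right = grow_cart(x[!left, , drop = FALSE], y[!left], lev,
                         depth + 1, max_depth, min_split, feats))
}

fit_cart <- function(x, y, lev, max_depth = 30, min_split = 2,
                     feats = seq_len(ncol(x))) {
  grow_cart(x, y, lev, 0L, max_depth, min_split, feats)
}

predict_cart_row <- function(tree, row) {
  while (!tree$leaf) {
    tree <- if (row[tree$feature] <= tree$threshold) tree$left else tree$right
  }
  tree$label
}

predict_cart <- function(tree, newx) {
  unname(apply(newx, 1, function(r) predict_cart_row(tree, r)))
}

## --- random forest (bagged subspace CART) ---------------------------------

fit_forest <- function(x, y, lev, seed, n_trees) {
  p <- ncol(x)
  mtry <- max(1L, floor(sqrt(p)))
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(b) {
      idx <- sample.int(length(y), replace = TRUE)
      feats <- sort(sample.int(p, mtry))
      fit_cart(x[idx, , drop = FALSE], y[idx], lev, feats = feats)
    })
    trees
  })
}

predict_forest <- function(trees, newx, lev) {
  votes <- matrix(0L, nrow(newx), length(lev), dimnames = list(NULL, lev))
  for (tr in trees) {
    pred <- predict_cart(tr, newx)
    for (i in seq_along(pred)) votes[i, pred[i]] <- votes[i, pred[i]] + 1L
  }
  lev[apply(votes, 1, which.max)]
}
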