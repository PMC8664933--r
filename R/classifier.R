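#' @name consang_classifier
#' @title Neural-net classification of parental relatedness
#'
#' @description
#' A single-hidden-layer feedforward network (15 inputs, H logistic hidden
#' units, softmax output over the ten union classes) maps an individual's
#' ROH feature vector ([extract_features()]) to a parental-relatedness
#' class. Training minimises the multinomial cross-entropy with a small L2
#' weight penalty by BFGS; everything is deterministic for a fixed seed.
NULL

# collapse map from the ten union classes to the three reported categories
#' Three-category collapse of the ten union classes
#'
#' "first cousin or closer" (sibling, all avuncular, all first-cousin
#' classes), "FCOR/second cousin", and "unrelated".
#'
#' @format named character vector mapping each of [union_classes] to its
#'   collapsed category.
#' @export
three_class_map <- c(
  sibling = "first_cousin_or_closer",
  avuncular_g1 = "first_cousin_or_closer",
  avuncular_g2 = "first_cousin_or_closer",
  avuncular_g3 = "first_cousin_or_closer",
  first_cousin_g1 = "first_cousin_or_closer",
  first_cousin_g2 = "first_cousin_or_closer",
  first_cousin_g3 = "first_cousin_or_closer",
  first_cousin_once_removed = "fcor_second_cousin",
  second_cousin = "fcor_second_cousin",
  unrelated = "unrelated")

# --- internal MLP ----------------------------------------------------------

.mlp_unpack <- function(theta, p, H, K) {
  n1 <- H * (p + 1)
  list(W1 = matrix(theta[seq_len(n1)], H, p + 1),
       W2 = matrix(theta[-seq_len(n1)], K, H + 1))
}

.mlp_forward <- function(W, X) {
  Z <- 1 / (1 + exp(-(cbind(1, X) %*% t(W$W1))))
  S <- cbind(1, Z) %*% t(W$W2)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  P <- E / rowSums(E)
  list(Z = Z, P = P)
}

.mlp_obj <- function(theta, X, Y, p, H, K, decay) {
  W <- .mlp_unpack(theta, p, H, K)
  fw <- .mlp_forward(W, X)
  n <- nrow(X)
  -sum(Y * log(pmax(fw$P, 1e-12))) / n + decay * sum(theta^2)
}

.mlp_grad <- function(theta, X, Y, p, H, K, decay) {
  W <- .mlp_unpack(theta, p, H, K)
  fw <- .mlp_forward(W, X)
  n <- nrow(X)
  D2 <- (fw$P - Y) / n                       # n x K
  G2 <- t(D2) %*% cbind(1, fw$Z)             # K x (H+1)
  D1 <- (D2 %*% W$W2[, -1, drop = FALSE]) * fw$Z * (1 - fw$Z)  # n x H
  G1 <- t(D1) %*% cbind(1, X)                # H x (p+1)
  c(as.vector(G1), as.vector(G2)) + 2 * decay * theta
}

#' Train the parental-relatedness classifier
#'
#' Samples `n_train_per_class` examples per class (without replacement)
#' from the supplied data, standardises features, and fits the network.
#'
#' @param features numeric matrix (individuals x 15).
#' @param labels character/factor vector of true union classes.
#' @param n_train_per_class training examples drawn per class (default 400).
#' @param hyper list overriding `list(hidden = 10, decay = 1e-4,
#'   maxit = 500)`.
#' @param seed integer seed (weight initialisation and the per-class
#'   training draw).
#' @return object of class `consang_classifier` holding weights, feature
#'   standardisation, class levels, the training row indices, and the
#'   optimiser's initial and final loss.
#' @export
train_classifier <- function(features, labels, n_train_per_class = 400,
                             hyper = list(), seed = 1) {
  hp <- utils::modifyList(list(hidden = 10L, decay = 1e-4, maxit = 500L,
                               sqrt_transform = TRUE), hyper)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  set.seed(seed)
  idx <- unlist(lapply(lev, function(cl) {
    w <- which(labels == cl)
    if (length(w) < n_train_per_class)
      stop("class ", cl, " has only ", length(w), " examples (< ",
           n_train_per_class, ")")
    sample(w, n_train_per_class)
  }))
  X <- as.matrix(features)[idx, , drop = FALSE]
  # counts and summed lengths are Poisson-like; the square root stabilises
  # their variance before standardisation
  if (hp$sqrt_transform) X <- sqrt(pmax(X, 0))
  y <- labels[idx]
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  K <- length(lev); p <- ncol(X); H <- hp$hidden
  Y <- outer(y, lev, "==") * 1
  theta0 <- stats::runif(H * (p + 1) + K * (H + 1), -0.5, 0.5)
  loss0 <- .mlp_obj(theta0, Xs, Y, p, H, K, hp$decay)
  # closures rather than `...` so that no argument can partial-match
  # optim's own formals (e.g. H -> hessian)
  fit <- stats::optim(theta0,
                      function(th) .mlp_obj(th, Xs, Y, p, H, K, hp$decay),
                      function(th) .mlp_grad(th, Xs, Y, p, H, K, hp$decay),
                      method = "BFGS",
                      control = list(maxit = hp$maxit, reltol = 1e-10))
  structure(list(W = .mlp_unpack(fit$par, p, H, K), center = ctr, scale = scl,
                 classes = lev, hidden = H, decay = hp$decay,
                 sqrt_transform = hp$sqrt_transform, seed = seed,
                 train_idx = idx, loss0 = loss0, loss = fit$value),
            class = "consang_classifier")
}

#' @export
print.consang_classifier <- function(x, ...) {
  cat(sprintf("<consang_classifier> %d classes, %d hidden units, loss %.4f (from %.4f)\n",
              length(x$classes), x$hidden, x$loss, x$loss0))
  invisible(x)
}

#' Predict union classes (single model)
#'
#' @param object a `consang_classifier`.
#' @param features matrix of feature vectors.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return character vector of classes, or a probability matrix whose rows
#'   sum to one.
#' @export
predict.consang_classifier <- function(object, features, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(features)
  if (isTRUE(object$sqrt_transform)) X <- sqrt(pmax(X, 0))
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  P <- .mlp_forward(object$W, Xs)$P
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' Majority-vote prediction across trial models
#'
#' Each individual is assigned the modal class across the trials' single
#' predictions; ties are broken toward the closer relationship (larger
#' expected offspring inbreeding coefficient), a deliberately conservative
#' choice for downstream use.
#'
#' @param trial_models list of `consang_classifier` models (default design
#'   uses 10 independent train/test resamples).
#' @param features matrix of feature vectors.
#' @return character vector of voted classes.
#' @export
predict_with_voting <- function(trial_models, features) {
  if (!length(trial_models)) stop("need at least one trial model")
  votes <- vapply(trial_models, predict, character(nrow(as.matrix(features))),
                  features = features)
  majority_vote(matrix(votes, nrow = nrow(as.matrix(features))))
}

#' @rdname predict_with_voting
#' @param votes character matrix, one row per individual, one column per
#'   trial.
#' @export
majority_vote <- function(votes) {
  closeness <- vapply(union_classes, function(cl)
    build_union_pedigree(cl)$expected_f, numeric(1))
  apply(votes, 1, function(v) {
    tb <- table(v)
    best <- names(tb)[tb == max(tb)]
    if (length(best) == 1L) return(best)
    ranked <- closeness[best]
    ranked[is.na(ranked)] <- -Inf   # unknown labels lose ties
    best[which.max(ranked)]
  })
}

#' Classification accuracy, optionally after collapsing classes
#'
#' @param predicted,truth character vectors of equal length.
#' @param collapse_map optional named map applied to both vectors before
#'   comparison (e.g. [three_class_map]); `NULL` compares the raw classes.
#' @return fraction of individuals classified correctly.
#' @export
evaluate_accuracy <- function(predicted, truth, collapse_map = NULL) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!is.null(collapse_map)) {
    predicted <- unname(collapse_map[predicted])
    truth <- unname(collapse_map[truth])
  }
  mean(predicted == truth)
}

#' Serialise a classifier to a flat text file
#'
#' Plain text: a header with dimensions and class list, then the weight
#' matrices and standardisation vectors, one value per line.
#'
#' @param model a `consang_classifier`.
#' @param path file path.
#' @export
write_classifier <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("p\t%d", length(model$center)),
               sprintf("hidden\t%d", model$hidden),
               sprintf("classes\t%s", paste(model$classes, collapse = ",")),
               sprintf("decay\t%.10g", model$decay),
               sprintf("sqrt_transform\t%d", as.integer(isTRUE(model$sqrt_transform)))), con)
  writeLines(format(c(as.vector(model$W$W1), as.vector(model$W$W2),
                      model$center, model$scale), digits = 17), con)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[1:5], "\t")
  p <- as.integer(hdr[[1]][2]); H <- as.integer(hdr[[2]][2])
  classes <- strsplit(hdr[[3]][2], ",")[[1]]
  decay <- as.numeric(hdr[[4]][2])
  sqrt_transform <- as.integer(hdr[[5]][2]) == 1L
  K <- length(classes)
  v <- as.numeric(ln[-(1:5)])
  n1 <- H * (p + 1); n2 <- K * (H + 1)
  structure(list(W = list(W1 = matrix(v[seq_len(n1)], H, p + 1),
                          W2 = matrix(v[n1 + seq_len(n2)], K, H + 1)),
                 center = v[n1 + n2 + seq_len(p)],
                 scale = v[n1 + n2 + p + seq_len(p)],
                 classes = classes, hidden = H, decay = decay,
                 sqrt_transform = sqrt_transform),
            class = "consang_classifier")
}

# --- consanguinity rates and kinship ---------------------------------------

#' Per-generation consanguinity rates from inferred class counts
#'
#' Converts counts of individuals assigned to each union class into the
#' per-generation rates r = (r1..r5) of parents being degree-1..5
#' relatives. Repeated-generation first-cousin classes contribute to
#' several components because, e.g., the offspring of a gen-2 first-cousin
#' union is also the offspring of second cousins by two routes and (gen-3)
#' of third cousins by three routes; the component sum may therefore
#' exceed 1.
#'
#' @param counts named numeric vector of per-class counts (names from
#'   [union_classes]; missing classes count 0).
#' @param n_individuals total individuals classified (default `sum(counts)`).
#' @return numeric r vector of length 5.
#' @export
estimate_r_from_counts <- function(counts, n_individuals = sum(counts)) {
  if (any(counts < 0)) stop("negative counts")
  if (n_individuals <= 0) stop("need a positive number of individuals")
  cnt <- function(cl) if (cl %in% names(counts)) counts[[cl]] else 0
  r1 <- cnt("sibling") / n_individuals
  r2 <- (cnt("first_cousin_g1") + cnt("first_cousin_g2") +
         cnt("first_cousin_g3")) / n_individuals
  r3 <- (cnt("first_cousin_once_removed") + 2 * cnt("first_cousin_g2") +
         2 * cnt("first_cousin_g3") + cnt("second_cousin")) / n_individuals
  r4 <- 3 * cnt("first_cousin_g3") / n_individuals
  c(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = 0)
}

#' Parental kinship from per-generation consanguinity rates
#'
#' k = sum_i r_i / 4^i: the probability that a random chromosome in each
#' parent coalesces due to consanguinity, under the single-connecting-path
#' model. The model requires k < 1/4.
#'
#' @param r numeric vector of rates (r1, r2, ...), any length up to 5 is
#'   padded with zeros.
#' @return the kinship k.
#' @export
kinship_from_r <- function(r) {
  if (any(r < 0)) stop("rates must be non-negative")
  if (length(r) > 5) stop("at most five rate components are supported")
  r <- c(r, numeric(5 - length(r)))
  k <- sum(r / 4^seq_len(5))
  if (k >= 0.25) stop("kinship k = ", signif(k, 4), " violates the model bound k < 1/4")
  k
}
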