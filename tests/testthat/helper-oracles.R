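# Independent brute-force oracles used to check the implementation paths.

# product-moment correlation from the explicit covariance/SD formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Mann-Whitney AUC by exhaustive pairwise concordance (ties counted 1/2),
# orientation "lower score = positive"
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p < q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# trapezoidal area under the empirical ROC curve
oracle_auc_trapezoid <- function(roc) {
  fpr <- 1 - roc$specificity
  o <- order(fpr, roc$sensitivity)
  x <- fpr[o]; y <- roc$sensitivity[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# one-way ANOVA F from hand-rolled sums of squares
oracle_anova_f <- function(groups) {
  all <- unlist(groups, use.names = FALSE)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# exhaustive enumeration of pixel centers strictly inside an ROI disc
oracle_roi_pixels <- function(center, radius, image_dim, spacing) {
  out <- NULL
  for (i in seq_len(image_dim[1])) {
    for (j in seq_len(image_dim[2])) {
      d2 <- ((i - 1) * spacing[1] - center[1])^2 +
        ((j - 1) * spacing[2] - center[2])^2
      if (d2 < radius^2) out <- rbind(out, c(i, j))
    }
  }
  out
}

# mean of the Rician distribution with noncentrality nu and scale sigma
oracle_rician_mean <- function(nu, sigma) {
  if (sigma == 0) return(nu)
  x <- nu^2 / (2 * sigma^2)
  L <- (1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
    x * besselI(x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * L
}

# analytic any-AS vs control AUC for Gaussian group-conditional ratios
oracle_mixture_auc <- function() {
  mu <- c(control = 1.01, mild = 0.83, moderate = 0.67, severe = 0.45)
  sd_ <- c(control = 0.19, mild = 0.14, moderate = 0.13, severe = 0.12)
  n <- c(mild = 66, moderate = 78, severe = 84)
  auc_g <- pnorm((mu["control"] - mu[names(n)]) /
                   sqrt(sd_["control"]^2 + sd_[names(n)]^2))
  sum(n * auc_g) / sum(n)
}
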