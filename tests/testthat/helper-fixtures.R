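# Small fixture builders shared across tests; everything is generated in
# code so tests carry no binary data.

# A tiny deterministic climate stack: `p` layers on an nr x nc unit grid.
tinyStack <- function(nr = 10, nc = 10, p = 3, seed = 42, scenario = "present") {
  set.seed(seed)
  layers <- lapply(seq_len(p), function(i)
    rasterGrid(matrix(rnorm(nr * nc, mean = i), nr, nc)))
  names(layers) <- sprintf("bio%02d", seq_len(p))
  climateStack(layers, scenario = scenario)
}

onesMask <- function(template) withValues(template,
  matrix(1, nrow(gridValues(template)), ncol(gridValues(template))))

# A linearly separable 1-D toy: presences at high predictor values.
separableToy <- function(n = 40, gap = 2, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n, gap), rnorm(n, -gap))
  labeledPoints("toy", coords = cbind(seq_along(x), 0),
                label = rep(c("presence", "pseudo_absence"), each = n),
                env = cbind(axis1 = x, axis2 = rnorm(2 * n, 0, 0.1)))
}

# Brute-force Jaccard scan oracle: best threshold over all unique scores.
bruteMaxJaccard <- function(scores, labels) {
  obs <- labels == "presence"
  best <- -1; bestT <- NA
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    tp <- sum(pred & obs); fp <- sum(pred & !obs); fn <- sum(!pred & obs)
    j <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
    if (j > best) { best <- j; bestT <- t }
  }
  list(threshold = bestT, jaccard = best)
}
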