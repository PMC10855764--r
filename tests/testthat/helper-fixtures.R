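# shared fixtures built in code

spme_factors <- function() {
  list(doe_factor("temp_c", 30, 50), doe_factor("time_min", 20, 60))
}

# the published 11-run layout: (temperature, time) pairs with the center
# replicated three times
spme_run_layout <- function() {
  rbind(c(40, 60), c(30, 60), c(40, 40), c(40, 40), c(30, 40), c(40, 20),
        c(40, 40), c(50, 40), c(50, 60), c(50, 20), c(30, 20))
}

# two linearly separable 2-D point clouds
separable_clouds <- function(n = 20, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * 2), ncol = 2),
               matrix(rnorm(n * 2, mean = gap), ncol = 2))
  })
  colnames(X) <- c("u", "v")
  list(X = X, labels = rep(c("neg", "pos"), each = n))
}

# brute-force AUROC: exhaustive concordant-pair counting
pairwise_auroc <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
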