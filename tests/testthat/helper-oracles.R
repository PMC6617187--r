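# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair counting, quadrature of the
# survival function, and explicit TP/FP tallies.

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-pairs concordance with ties counted 1/2
cindex_bruteforce <- function(pred, y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + if (pred[i] > pred[j]) 1 else if (pred[i] == pred[j]) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# mean survival by adaptive quadrature of S(t) = exp(-(t/scale)^shape)
weibull_mean_quadrature <- function(shape, scale, upper = Inf) {
  stats::integrate(function(t) exp(-(t / scale)^shape), 0, upper,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

# mean of an arbitrary survival function by quadrature
weibull_mean_quadrature_fn <- function(s_fun, upper = 200) {
  stats::integrate(s_fun, 0, upper, rel.tol = 1e-10, subdivisions = 500L)$value
}

# explicit counting version of net benefit
net_benefit_bruteforce <- function(pred, y, t) {
  n <- length(y)
  tp <- 0; fp <- 0
  for (i in seq_len(n)) {
    if (pred[i] >= t) {
      if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1
    }
  }
  tp / n - t / (1 - t) * fp / n
}

# discrete yearly simulation of deaths under a life-table hazard divided by
# `ratio`; returns a survival-cohort data frame (ages advance annually)
simulate_lifetable_cohort <- function(n, life_table, ratio, horizon_years = 15,
                                      age_range = c(58, 72)) {
  age0 <- floor(runif(n, age_range[1], age_range[2] + 1))
  fu <- numeric(n)
  dead <- logical(n)
  haz <- function(a) {
    life_table$hazard[pmin(pmax(a - life_table$age[1] + 1, 1),
                           nrow(life_table))]
  }
  for (i in seq_len(n)) {
    t <- 0
    repeat {
      if (t >= horizon_years) { fu[i] <- horizon_years; break }
      p_die <- 1 - exp(-haz(age0[i] + t) / ratio)
      if (runif(1) < p_die) {
        fu[i] <- t + runif(1)  # death uniform within the year
        dead[i] <- TRUE
        break
      }
      t <- t + 1
    }
  }
  data.frame(age = age0, charlson = sample(c("0", "1", "2+"), n, TRUE,
                                           prob = c(0.6, 0.25, 0.15)),
             follow_up_months = fu * 12,
             status = ifelse(dead, "dead", "alive"),
             stringsAsFactors = FALSE)
}
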