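# Shared fixtures: tiny cohort specs and fast network configurations used
# across the module tests. All fixtures are built in code at test time.

# A compact feature inventory with one strong hazard driver, a weaker one,
# and pure-noise indicators.
tiny_features <- function(n_noise = 6) {
  noise <- do.call(rbind, lapply(seq_len(n_noise), function(i) {
    feature_spec(sprintf("noise_%02d", i), "binary", 0.3, 0.3)
  }))
  rbind(
    feature_spec("driver", "binary", 0.25, 0.70, hazard_weight = 1.5),
    feature_spec("helper", "binary", 0.35, 0.50, hazard_weight = 0.5),
    feature_spec("marker", "continuous", mean_survival = 0, sd_survival = 1,
                 mean_death = 1, sd_death = 1, hazard_weight = 0.3),
    noise
  )
}

tiny_spec <- function(n_total = 400, n_censored = 120, seed = 1,
                      death_fraction = 0.3, ...) {
  cohort_spec(n_total, n_censored, death_fraction, tiny_features(),
              baseline_hazard = 0.02, seed = seed, ...)
}

# Small, quickly trainable network for unit tests (fixture scale, not the
# reference architecture).
fast_cfg <- function(input_dim, seed = 1, epochs = 200, ...) {
  net_config(input_dim = input_dim, hidden = c(16, 16), batch_size = 16,
             learning_rate = 0.05, epochs = epochs, seed = seed, ...)
}

fast_loss <- function() loss_config(alpha_f = 3, t1 = 20, t2 = 100)

# Linearly separable two-blob fixture.
separable_fixture <- function(n = 120, d = 4, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(n * d, sd = 0.15), n, d) + 0.5
  X[, 1] <- X[, 1] + ifelse(y == 1, 0.35, -0.35)
  X <- pmin(pmax(X, 0), 1)
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = y)
}

# Independent scalar-loop implementation of the combined loss, used as the
# oracle against the vectorized implementation.
naive_combined_loss <- function(true_labels, true_outputs, pseudo_labels,
                                pseudo_outputs, t, cfg) {
  term <- function(labels, outputs) {
    n <- length(labels)
    Np <- 0; Nn <- 0
    for (l in labels) if (l == 1) Np <- Np + 1 else Nn <- Nn + 1
    zw <- Np / n; ow <- Nn / n
    total <- 0
    for (i in seq_len(n)) {
      y <- if (labels[i] == 1) c(0, 1) else c(1, 0)
      w <- if (labels[i] == 1) ow else zw
      se <- 0
      for (k in 1:2) se <- se + (y[k] - outputs[i, k])^2
      total <- total + w * se
    }
    total / (2 * n)
  }
  a <- if (t < cfg$t1) 0
       else if (t <= cfg$t2) cfg$alpha_f * (t - cfg$t1) / (cfg$t2 - cfg$t1)
       else cfg$alpha_f
  lt <- unname(term(true_labels, true_outputs))
  if (is.null(pseudo_labels) || length(pseudo_labels) == 0) return(lt)
  unname(lt + a * term(pseudo_labels, pseudo_outputs))
}

random_prob_rows <- function(n) {
  p <- stats::runif(n)
  cbind(1 - p, p)
}
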