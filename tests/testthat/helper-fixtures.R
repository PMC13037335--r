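# Shared fixtures and independent oracles. The oracles are deliberately
# written in the most literal style possible (explicit loops, textbook
# formulas) and never share code with the implementation they check.

# textbook Pearson correlation: covariance over product of SDs
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  cov_xy <- sum((x - mx) * (y - my)) / (length(x) - 1)
  sd_x <- sqrt(sum((x - mx)^2) / (length(x) - 1))
  sd_y <- sqrt(sum((y - my)^2) / (length(y) - 1))
  cov_xy / (sd_x * sd_y)
}

# naive double-loop polyconnectomic score over the square matrices
naive_pcs <- function(fc_mat, weight_mat) {
  p <- nrow(fc_mat)
  total <- 0
  n <- 0L
  for (i in seq_len(p - 1)) {
    for (j in seq.int(i + 1, p)) {
      if (weight_mat[i, j] != 0) {
        total <- total + weight_mat[i, j] * fc_mat[i, j]
        n <- n + 1L
      }
    }
  }
  total / n
}

# quick template on p parcels with the given canonical-order weights
tiny_template <- function(weights, p = NULL, n_networks = 1L,
                          template_id = "tiny") {
  if (is.null(p)) {
    p <- as.integer(round((1 + sqrt(1 + 8 * length(weights))) / 2))
  }
  labels <- paste0("p", seq_len(p))
  nets <- paste0("net", rep_len(seq_len(n_networks), p))
  css_template(weights, parcel_labels = labels,
               network_partition = stats::setNames(nets, labels),
               template_id = template_id)
}

# random sparse template on p parcels (weights ~ N(0,1), about half non-zero)
random_template <- function(p, seed, frac_nonzero = 0.5) {
  withr::with_seed(seed, {
    e <- n_edges(p)
    w <- stats::rnorm(e)
    w[stats::runif(e) > frac_nonzero] <- 0
    if (all(w == 0)) w[1L] <- 1
    tiny_template(w, p = p, n_networks = 2L)
  })
}

# random symmetric correlation-like matrix with unit diagonal
random_fc <- function(p, seed, subject_id = "rnd") {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(p * 40L), 40L, p)
    fc_matrix(stats::cor(x), subject_id = subject_id)
  })
}

# small cohort table for change-score unit tests
two_timepoint_cohort <- function() {
  tibble::tibble(
    subject_id = c("s1", "s1", "s2", "s3", "s3"),
    family_id = c("f1", "f1", "f1", "f2", "f2"),
    timepoint = c("baseline", "followup", "baseline", "baseline", "followup"),
    age = c(10, 11.5, 10, 12, 13.2),
    sex = c(0, 0, 1, 1, 1),
    stress = c(20, 27, 15, 30, 24),
    anxiety = c(10, 12, 8, 20, 22),
    depression = c(3, 5, 2, 7, 6)
  )
}
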