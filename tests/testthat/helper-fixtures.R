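# Fixtures and independent brute-force oracles. The oracles use explicit
# loops and share no code with the package, so agreement is a real check.

worked_example_set <- function() {
  sample_set(data.frame(
    individual_id = c("A", "A", "B", "B"),
    province = "P1", habitat = "coastal", age = "adult",
    tissue = c("muscle", "collagen", "muscle", "collagen"),
    d13c = c(-20, -18, -24, -24), d15n = c(8, 10, 6, 6),
    stringsAsFactors = FALSE), provenance = "worked example")
}

# random but structurally valid sample set: each individual gets a random
# non-empty subset of tissues, consistent factors, <= 200 samples
random_sample_set <- function(seed, max_individuals = 80) {
  set.seed(seed)
  n_ind <- sample(3:max_individuals, 1)
  rows <- list()
  for (i in seq_len(n_ind)) {
    habitat <- sample(c("coastal", "inland"), 1)
    age <- sample(c("adult", "juvenile"), 1)
    province <- sample(sprintf("P%d", 1:8), 1)
    tissues <- sample(c("fur", "muscle", "collagen"),
                      sample(1:3, 1))
    for (t in tissues) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("I%03d", i), province = province,
        habitat = habitat, age = age, tissue = t,
        d13c = rnorm(1, -21, 3), d15n = rnorm(1, 9, 2.5),
        stringsAsFactors = FALSE)
    }
  }
  sample_set(do.call(rbind, rows), provenance = sprintf("random seed %d", seed))
}

# brute-force centroid distances: explicit loops, no vectorised shortcuts
oracle_centroid_distances <- function(df, use_tissue = TRUE) {
  out <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    sum_c <- 0; sum_n <- 0; count <- 0
    for (j in seq_len(nrow(df))) {
      same <- df$habitat[j] == df$habitat[i] && df$age[j] == df$age[i]
      if (use_tissue) same <- same && df$tissue[j] == df$tissue[i]
      if (same) {
        sum_c <- sum_c + df$d13c[j]
        sum_n <- sum_n + df$d15n[j]
        count <- count + 1
      }
    }
    out[i] <- sqrt((df$d13c[i] - sum_c / count)^2 +
                   (df$d15n[i] - sum_n / count)^2)
  }
  out
}

# brute-force WIC and TNW on the muscle+collagen paired subset of one
# habitat x age group
oracle_wic_tnw <- function(df, habitat, age) {
  keep <- df$habitat == habitat & df$age == age &
    df$tissue %in% c("muscle", "collagen")
  sub <- df[keep, , drop = FALSE]
  ids <- unique(sub$individual_id)
  paired <- character()
  for (id in ids) {
    tis <- sub$tissue[sub$individual_id == id]
    if (any(tis == "muscle") && any(tis == "collagen"))
      paired <- c(paired, id)
  }
  sub <- sub[sub$individual_id %in% paired, , drop = FALSE]
  wd <- numeric(0)
  for (id in paired) {
    rows <- sub[sub$individual_id == id, ]
    cc <- mean(rows$d13c); cn <- mean(rows$d15n)
    for (r in seq_len(nrow(rows)))
      wd <- c(wd, sqrt((rows$d13c[r] - cc)^2 + (rows$d15n[r] - cn)^2))
  }
  gc_c <- mean(sub$d13c); gc_n <- mean(sub$d15n)
  td <- numeric(0)
  for (r in seq_len(nrow(sub)))
    td <- c(td, sqrt((sub$d13c[r] - gc_c)^2 + (sub$d15n[r] - gc_n)^2))
  list(wic = mean(wd), tnw = mean(td), ratio = mean(wd) / mean(td))
}

# minimal noiseless config: direct alpha in every cell, no offsets/noise
noiseless_config <- function(alpha, seed = 1L, n = 2L) {
  cell <- list(n = n, alpha_mean = alpha, alpha_conc = 50, sigma_w = 0)
  sim_config(groups = list(coastal_adult = cell, coastal_juvenile = cell,
                           inland_adult = cell, inland_juvenile = cell),
             tissue_offsets = rbind(fur = c(0, 0), muscle = c(0, 0),
                                    collagen = c(0, 0)),
             sigma_m = 0, province_sd = 0, seed = seed)
}
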