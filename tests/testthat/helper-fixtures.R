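# Fixture builders and independent oracles shared across the suite.

# build a geno_matrix from a plain numeric matrix, auto-naming axes
gm <- function(m, samples = NULL, markers = NULL) {
  m <- as.matrix(m)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(markers)) markers <- sprintf("M%03d", seq_len(ncol(m)))
  dimnames(m) <- list(samples, markers)
  storage.mode(m) <- "integer"
  geno_matrix(m)
}

# brute-force double-loop IBS oracle (per-locus allele sharing 0/0.5/1)
brute_ibs <- function(X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      keep <- !is.na(X[i, ]) & !is.na(X[j, ])
      if (!any(keep)) next
      score <- 1 - abs(X[i, keep] - X[j, keep]) / 2
      out[i, j] <- mean(score)
    }
  }
  out
}

# adjusted Rand index straight from the contingency-table formula
ari_oracle <- function(a, b) {
  ct <- table(a, b)
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# independent Ward agglomeration (Lance-Williams update for ward.D2),
# returning flat labels after stopping at k clusters
ward_oracle_labels <- function(D, k) {
  n <- nrow(D)
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  d <- D
  diag(d) <- Inf
  while (length(active) > k) {
    sub <- d[active, active]
    idx <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[idx[1]]; j <- active[idx[2]]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dij <- d[i, j]
    for (h in setdiff(active, c(i, j))) {
      nik <- sizes[i] + sizes[h]; njk <- sizes[j] + sizes[h]
      ntot <- sizes[i] + sizes[j] + sizes[h]
      d[i, h] <- d[h, i] <- sqrt((nik * d[i, h]^2 + njk * d[j, h]^2 -
                                    sizes[h] * dij^2) / ntot)
    }
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  labels <- integer(n)
  for (c in seq_along(active)) labels[members[[active[c]]]] <- c
  labels
}

# hand-built six-rule fixture: a small library plus field samples that
# trigger each decision rule exactly once (200 het-free markers)
make_rule_fixture <- function() {
  set.seed(42)
  m <- 200
  rand_geno <- function() 2L * stats::rbinom(m, 1L, runif(m, 0.2, 0.8))
  perturb <- function(g, k) {
    idx <- sample.int(m, k)
    g[idx] <- 2L - g[idx]
    g
  }
  A <- rand_geno(); B <- rand_geno(); C <- rand_geno(); D <- rand_geno()
  lib <- rbind(
    A = A,
    B_s1 = B, B_s2 = B, B_s3 = B,
    G = B,                                  # same profile as B, its own name
    C_s1 = C, C_s2 = perturb(C, 40),
    D_s1 = D, D_s2 = perturb(D, 40), D_s3 = perturb(D, 80),
    D_s4 = perturb(D, 120)
  )
  far1 <- rand_geno(); far2 <- rand_geno(); far3 <- rand_geno()
  fld <- rbind(
    f_r1 = A,                               # unique match -> R1
    f_r2 = B,                               # concordant duplicates + alias -> R2
    f_r3 = C,                               # one of two discordant sources -> R3
    f_r4a = D, f_r4b = D,                   # many-dup discordant, cohesive -> R4
    f_r5a = far1, f_r5b = far1,             # no match, cohesive cohort -> R5
    f_r6a = far2, f_r6b = far3              # no match, discordant cohort -> R6
  )
  calls <- rbind(lib, fld)
  colnames(calls) <- sprintf("M%03d", seq_len(m))
  g <- geno_matrix(calls)
  records <- tibble::tibble(
    sample_id = rownames(calls),
    role = c(rep("reference", nrow(lib)), rep("field", nrow(fld))),
    reported_name = c("A", "B", "B", "B", "G", "C", "C", "D", "D", "D", "D",
                      "A", "B", "C", "D", "D", "E", "E", "F", "F"),
    pedigree = paste0("PED_", c("A", "B", "B", "B", "G", "C", "C",
                                "D", "D", "D", "D",
                                rep(NA, nrow(fld))))
  )
  list(genotypes = g, records = records,
       thresholds = identity_thresholds(initial = 0.998, minimum = 0.991))
}
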