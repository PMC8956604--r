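# Cytolytic activity, Fisher-z correlation, ssGSEA, responder comparison.

# cohort with explicitly chosen expression rows (log2 scale)
manual_cohort <- function(rows, dataset = "d1", response = NULL) {
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  meta <- data.frame(sample_id = colnames(m), dataset_id = dataset,
                     stringsAsFactors = FALSE)
  if (!is.null(response)) meta$response <- response
  expression_cohort(m, meta, scale = "log2")
}

test_that("cytolytic activity is the offset geometric mean of GZMA and PRF1", {
  # log2 cohort: s1 has both markers at linear 3, s2 at linear 10
  coh <- expression_cohort(
    matrix(c(2, log2(11), 2, log2(11), 0, 0), nrow = 3, byrow = TRUE,
           dimnames = list(c("GZMA", "PRF1", "OTHER"), c("s1", "s2"))),
    data.frame(sample_id = c("s1", "s2"), dataset_id = "d"), scale = "log2")
  cyt <- cytolytic_activity(coh, offset = 0)
  expect_equal(unname(cyt["s1"]), 3)   # equal markers -> that value
  expect_equal(unname(cyt["s2"]), 10)
  # GZMA 4, PRF1 9 on the linear scale -> 6
  coh2 <- expression_cohort(
    matrix(c(4, 1, 9, 1), nrow = 2, byrow = TRUE,
           dimnames = list(c("GZMA", "PRF1"), c("s1", "s2"))),
    data.frame(sample_id = c("s1", "s2"), dataset_id = "d"), scale = "linear")
  expect_equal(unname(cytolytic_activity(coh2, offset = 0)["s1"]), 6)
  # zero expression floors at the offset
  coh3 <- expression_cohort(
    matrix(0, 2, 2, dimnames = list(c("GZMA", "PRF1"), c("s1", "s2"))),
    data.frame(sample_id = c("s1", "s2"), dataset_id = "d"), scale = "linear")
  expect_equal(unname(cytolytic_activity(coh3, offset = 0.01)["s1"]), 0.01)
  expect_error(cytolytic_activity(manual_cohort(list(A = rep(1, 4)))), "GZMA")
})

test_that("Fisher-z p-values match the normal-tail oracle", {
  # build a gene with exact sample correlation r = 0.5 against the cytolytic
  # axis at n = 103 via Gram-Schmidt
  n <- 103
  set.seed(31)
  a <- scale(rnorm(n))[, 1]
  b <- rnorm(n); b <- b - a * sum(a * b) / sum(a * a); b <- scale(b)[, 1]
  g <- 0.5 * a + sqrt(1 - 0.25) * b
  coh <- manual_cohort(list(GZMA = 3 + a, PRF1 = 3 + a, TESTG = 3 + g,
                            FLAT = rep(2, n)))
  cyt <- cytolytic_activity(coh)
  expect_message(rows <- correlate_gene_cytolytic(coh, cyt), "zero-variance")
  tg <- rows[rows$gene_symbol == "TESTG", ]
  # correlation against log2(CYT + 1): near-exact recovery of r = 0.5
  expect_equal(tg$r, 0.5, tolerance = 0.01)
  z <- atanh(tg$r) * sqrt(n - 3)
  expect_equal(tg$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  expect_lt(tg$p, 1e-6)
  expect_true(tg$significant_positive)
  # zero-variance gene: r undefined, p = 1
  fl <- rows[rows$gene_symbol == "FLAT", ]
  expect_true(is.na(fl$r))
  expect_equal(fl$p, 1)
  expect_false(fl$significant_positive)
})

test_that("a gene identical to the cytolytic axis floors at the smallest p", {
  n <- 50
  set.seed(32)
  a <- rnorm(n)
  coh <- manual_cohort(list(GZMA = 3 + a, PRF1 = 3 + a,
                            SAME = log2(sqrt((2^(3 + a) - 1 + 0.01) *
                                               (2^(3 + a) - 1 + 0.01)) + 1)))
  rows <- correlate_gene_cytolytic(coh)
  same <- rows[rows$gene_symbol == "SAME", ]
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_equal(same$p, .Machine$double.xmin)
})

test_that("Fisher-z p agrees with a permutation p within a factor of two", {
  n <- 100
  set.seed(33)
  a <- scale(rnorm(n))[, 1]
  b <- rnorm(n); b <- b - a * sum(a * b) / sum(a * a); b <- scale(b)[, 1]
  g <- 0.3 * a + sqrt(1 - 0.09) * b
  r_obs <- cor(g, a)
  p_fisher <- 2 * pnorm(-abs(atanh(r_obs) * sqrt(n - 3)))
  null_r <- replicate(10000, abs(cor(g, sample(a))))
  p_perm <- (1 + sum(null_r >= abs(r_obs))) / (1 + 10000)
  expect_lt(max(p_fisher / p_perm, p_perm / p_fisher), 2)
})

test_that("pan-cancer summary counts significant tumor types per gene", {
  rows <- data.frame(
    gene_symbol = rep(c("A", "B", "C"), each = 33),
    tumor_type = rep(sprintf("T%02d", 1:33), 3),
    significant_positive = c(rep(FALSE, 33),
                             c(rep(TRUE, 9), rep(FALSE, 24)),
                             c(TRUE, rep(FALSE, 32))),
    stringsAsFactors = FALSE)
  s <- summarize_pan_cancer(rows)
  a <- s[s$gene_symbol == "A", ]; b <- s[s$gene_symbol == "B", ]
  c_ <- s[s$gene_symbol == "C", ]
  expect_equal(a$fraction, 0); expect_false(a$any_type); expect_false(a$over_quarter)
  expect_equal(b$fraction, 9 / 33); expect_true(b$over_quarter)
  expect_true(c_$any_type); expect_false(c_$over_quarter)
})

test_that("patient replicate averaging collapses columns and metadata", {
  coh <- manual_cohort(list(GZMA = c(1, 2, 5), PRF1 = c(2, 4, 6)),
                       response = c("responder", "responder", "nonresponder"))
  map <- c(s001 = "P1", s002 = "P1", s003 = "P2")
  avg <- average_patient_replicates(coh, map)
  expect_equal(dim(avg$values), c(2L, 2L))
  expect_equal(unname(avg$values["GZMA", "P1"]), 1.5)  # mean of 1 and 2
  expect_equal(unname(avg$values["GZMA", "P2"]), 5)    # single sample unchanged
  expect_equal(avg$metadata$response, c("responder", "nonresponder"))
  # permuting sample order gives the same collapsed values
  coh2 <- coh
  coh2$values <- coh2$values[, c(3, 1, 2)]
  coh2$metadata <- coh2$metadata[c(3, 1, 2), ]
  avg2 <- average_patient_replicates(expression_cohort(
    coh2$values, coh2$metadata, "log2"), map)
  expect_equal(avg2$values[, c("P1", "P2")], avg$values[, c("P1", "P2")])
  # conflicting labels within a patient
  coh3 <- manual_cohort(list(GZMA = c(1, 2), PRF1 = c(1, 2)),
                        response = c("responder", "nonresponder"))
  expect_error(average_patient_replicates(coh3, c(s001 = "P1", s002 = "P1")),
               "conflicting")
})

test_that("ssGSEA reproduces the unweighted single-gene worked example", {
  coh <- manual_cohort(list(G1 = c(4, 1), G2 = c(3, 4), G3 = c(2, 3),
                            G4 = c(1, 2)))
  sc <- ssgsea_score(coh, "G1", weight = 0)
  # sample 1: G1 on top -> ES = (1-0) + (1-1/3) + (1-2/3) + (1-1) = 2
  expect_equal(sc$es[1], 2.0, tolerance = 1e-12)
  # sample 2: G1 at the bottom -> ES = (0-1/3) + (0-2/3) + (0-1) + (1-1) = -2
  expect_equal(sc$es[2], -2.0, tolerance = 1e-12)
  expect_equal(sc$nes, sc$es / 4)
  expect_error(ssgsea_score(coh, c("G1", "G2", "G3", "G4")), "every cohort gene")
  expect_error(ssgsea_score(coh, "ABSENT"), "intersect")
})

test_that("ssGSEA with weight 0 is invariant to monotone transforms", {
  set.seed(41)
  m <- matrix(rnorm(200, 5, 1), nrow = 20,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("s%02d", 1:10)))
  meta <- data.frame(sample_id = colnames(m), dataset_id = "d")
  c1 <- expression_cohort(m, meta, "log2")
  c2 <- expression_cohort(m^3 + 1, meta, "log2")
  sig <- sprintf("G%02d", 1:5)
  expect_equal(ssgsea_score(c1, sig, weight = 0)$es,
               ssgsea_score(c2, sig, weight = 0)$es, tolerance = 1e-12)
})

test_that("ssGSEA matches the brute-force ECDF oracle to 1e-9", {
  set.seed(43)
  for (case in 1:5) {
    n_genes <- 50
    m <- matrix(rnorm(n_genes * 4, 4, 2), nrow = n_genes,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("s%d", 1:4)))
    meta <- data.frame(sample_id = colnames(m), dataset_id = "d")
    coh <- expression_cohort(m, meta, "log2")
    sig <- sample(rownames(m), sample(3:20, 1))
    w <- sample(c(0, 0.25, 1), 1)
    sc <- ssgsea_score(coh, sig, weight = w)
    for (j in 1:4) {
      x <- m[, j]
      expect_equal(sc$es[j], oracle_ssgsea_es(x, sig, w), tolerance = 1e-9)
    }
  }
})

test_that("z-scoring operates within datasets", {
  sc <- data.frame(sample_id = sprintf("s%d", 1:6),
                   dataset_id = rep(c("d1", "d2"), each = 3),
                   nes = c(1, 2, 3, 11, 12, 16), stringsAsFactors = FALSE)
  z <- zscore_by_dataset(sc)
  expect_equal(z$z[1:3], c(-1, 0, 1))
  expect_equal(mean(z$z[4:6]), 0, tolerance = 1e-12)
  expect_equal(sd(z$z[4:6]), 1, tolerance = 1e-12)
  sc$nes <- rep(2, 6)
  expect_error(zscore_by_dataset(sc), "zero NES variance")
  expect_error(zscore_by_dataset(data.frame(dataset_id = "d1", nes = 1)),
               "fewer than 2")
})

test_that("response comparison is symmetric and null at identical groups", {
  sc <- data.frame(z = c(1, 2, 3, 1, 2, 3),
                   response = rep(c("responder", "nonresponder"), each = 3),
                   stringsAsFactors = FALSE)
  out <- compare_response_groups(sc)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  # swapping labels flips the sign and keeps the p-value
  sc2 <- data.frame(z = c(0.5, 1.1, 0.2, 2.5, 3.0, 2.2),
                    response = rep(c("responder", "nonresponder"), each = 3),
                    stringsAsFactors = FALSE)
  o1 <- compare_response_groups(sc2)
  sc3 <- sc2
  sc3$response <- rev(sc2$response)
  o2 <- compare_response_groups(sc3)
  expect_equal(o1$p_value, o2$p_value)
  expect_equal(o1$statistic, -o2$statistic)
  expect_equal(o1$higher_group, "nonresponder")
  expect_error(compare_response_groups(
    data.frame(z = c(1, 2, 3), response = c("responder", "nonresponder",
                                            "nonresponder"))), "at least 2")
})
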