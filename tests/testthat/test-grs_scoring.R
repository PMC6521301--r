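test_that("allelic odds ratio and direction follow the coding rule", {
  # non-responders 40 minor / 60 major; responders 20 / 80
  dosages <- c(rep(2, 20), rep(0, 30), rep(2, 10), rep(0, 40))
  resp <- c(rep(FALSE, 50), rep(TRUE, 50))
  w <- allele_odds_ratio(dosages, resp)
  expect_equal(w$table,
               c(minor_nr = 40, major_nr = 60, minor_r = 20, major_r = 80))
  expect_equal(w$odds_ratio, (40 / 60) / (20 / 80), tolerance = 1e-12)
  expect_equal(w$odds_ratio, 2.667, tolerance = 1e-3)
  expect_equal(w$direction, 1L)
  expect_false(w$haldane)

  # identical allele frequencies: OR exactly 1, direction 0
  eq <- allele_odds_ratio(c(1, 1, 0, 1, 1, 0),
                          c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(eq$odds_ratio, 1)
  expect_equal(eq$direction, 0L)

  # minor allele absent among non-responders: Haldane correction, OR < 1
  h <- allele_odds_ratio(c(0, 0, 0, 1, 2, 0),
                         c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(h$haldane)
  t2 <- h$table + 0.5
  expect_equal(h$odds_ratio,
               (t2[["minor_nr"]] / t2[["major_nr"]]) /
                 (t2[["minor_r"]] / t2[["major_r"]]))
  expect_lt(h$odds_ratio, 1)
  expect_equal(h$direction, -1L)
})

test_that("odds ratios match the direct cross-ratio on random tables", {
  set.seed(51)
  for (i in 1:100) {
    n <- 60
    dos <- rbinom(n, 2, runif(1, 0.1, 0.5))
    resp <- rbinom(n, 1, 0.5) == 1
    if (!any(resp) || all(resp)) next
    w <- allele_odds_ratio(dos, resp)
    minor_nr <- sum(dos[!resp]); major_nr <- 2 * sum(!resp) - minor_nr
    minor_r <- sum(dos[resp]); major_r <- 2 * sum(resp) - minor_r
    tab <- c(minor_nr, major_nr, minor_r, major_r)
    if (any(tab == 0)) tab <- tab + 0.5
    expect_equal(w$odds_ratio, (tab[1] / tab[2]) / (tab[3] / tab[4]),
                 tolerance = 1e-12)
    # inverting responder labels inverts the odds ratio
    inv <- allele_odds_ratio(dos, !resp)
    expect_equal(inv$odds_ratio, 1 / w$odds_ratio, tolerance = 1e-9)
    if (w$direction != 0L) expect_equal(inv$direction, -w$direction)
  }
})

test_that("scores are signed dosage sums with the documented symmetries", {
  set.seed(52)
  dos <- matrix(rbinom(200, 2, 0.35), 20, 10)
  gm <- make_gm(dos)
  w0 <- data.frame(rsid = gm$snps$rsid, direction = 0L)
  expect_true(all(compute_grs(gm, w0)$score == 0L))

  # one-SNP panel, direction +1, homozygous minor participant scores +2
  w1 <- data.frame(rsid = gm$snps$rsid, direction = 1L)
  g1 <- compute_grs(gm, w1, panel = gm$snps$rsid[1])
  expect_equal(g1$score, unname(dos[, 1]))

  gw <- data.frame(rsid = gm$snps$rsid,
                   direction = sample(c(-1L, 0L, 1L), 10, replace = TRUE))
  g <- compute_grs(gm, gw)
  expect_true(all(abs(g$score) <= 2 * 10))
  expect_true(all(g$score == round(g$score)))
  # negating every direction negates every score
  gneg <- gw; gneg$direction <- -gneg$direction
  expect_equal(compute_grs(gm, gneg)$score, -g$score)
  # linearity over a partition of the panel
  pa <- gm$snps$rsid[1:4]; pb <- gm$snps$rsid[5:10]
  expect_equal(compute_grs(gm, gw, panel = pa)$score +
                 compute_grs(gm, gw, panel = pb)$score, g$score)
  # permuting participants permutes scores identically
  perm <- sample(20)
  gmp <- genotype_matrix(dos[perm, ], gm$snps,
                         participant_ids = gm$participant_ids[perm])
  gp <- compute_grs(gmp, gw)
  expect_equal(gp$score[match(g$participant_id, gp$participant_id)],
               g$score)
  # carrier mode caps each SNP contribution at one
  gc <- compute_grs(gm, w1, mode = "carrier")
  expect_equal(gc$score, unname(rowSums(pmin(dos, 1))))
})

test_that("participants missing a panel genotype are left unscored", {
  dos <- matrix(rbinom(100, 2, 0.3), 20, 5)
  dos[7, 3] <- NA
  gm <- make_gm(dos)
  w <- data.frame(rsid = gm$snps$rsid, direction = 1L)
  g <- compute_grs(gm, w)
  expect_true(is.na(g$score[7]))
  expect_equal(g$n_missing[7], 1)
  expect_equal(attr(g, "n_scored"), 19)
  h <- grs_distribution(g)
  expect_equal(attr(h, "n"), 19)
  expect_error(compute_grs(gm, w, panel = "rs_unknown"), "rs_unknown")
  expect_error(compute_grs(gm, w[-1, ], panel = gm$snps$rsid), "rs1")
})

test_that("replication panel wrapper uses the seven fixed SNPs", {
  coh <- simulate_cohort(simulation_config(seed = 53))
  ph <- classify_responders(coh$phenotypes)
  w <- compute_weights(coh$genotypes, ph)
  g7 <- replication_panel_grs(coh$genotypes, w)
  expect_setequal(attr(g7, "rsids"), replication_panel())
  expect_equal(g7$score,
               compute_grs(coh$genotypes, w,
                           panel = replication_panel())$score)
})

test_that("score histogram counts integer scores", {
  g <- structure(data.frame(participant_id = c("a", "b", "c"),
                            score = c(0L, 0L, 1L), n_missing = 0L),
                 panel_name = "toy", rsids = "rs1", n_scored = 3L,
                 class = c("grs_vector", "data.frame"))
  h <- grs_distribution(g)
  expect_equal(h$count[h$score == 0], 2)
  expect_equal(h$count[h$score == 1], 1)
  expect_equal(attr(h, "n"), 3)
})

test_that("direction recovery improves with planted effect size", {
  frac_correct <- function(effect, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- simulation_config(
        causal_snps = data.frame(rsid = refined_panel(),
                                 effect = rep(effect, 5)),
        target_grs_partial_r2 = 0.2, seed = s)
      coh <- simulate_cohort(cfg)
      ph <- classify_responders(coh$phenotypes)
      w <- compute_weights(coh$genotypes, ph)
      mean(w$direction[match(refined_panel(), w$rsid)] == 1L)
    }, numeric(1)))
  }
  # same planted variance fraction, but more of it per SNP at larger
  # effect size; direction calls should be right more often than chance
  # and improve as n grows
  lo <- frac_correct(6, 1:15)
  expect_gt(lo, 0.5)
  big_n <- mean(vapply(1:10, function(s) {
    cfg <- simulation_config(
      n_participants = 800,
      causal_snps = data.frame(rsid = refined_panel(),
                               effect = rep(6, 5)),
      target_grs_partial_r2 = 0.2, seed = 100 + s)
    coh <- simulate_cohort(cfg)
    ph <- classify_responders(coh$phenotypes)
    w <- compute_weights(coh$genotypes, ph)
    mean(w$direction[match(refined_panel(), w$rsid)] == 1L)
  }, numeric(1)))
  expect_gt(big_n, lo)
})
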