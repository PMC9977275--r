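mk_gcn <- function(cn, marker, species = "spX") {
  # build a gene matrix whose copy numbers are exactly `cn` given `marker`
  cov <- sweep(cn, 2, marker, `*`)
  gene_cn_matrix(species, cov, marker)
}

test_that("copy number is coverage over marker median, guarded at zero", {
  expect_equal(copy_number(12, 24), 0.5)
  expect_equal(copy_number(0, 24), 0)
  expect_true(is.na(copy_number(10, 0)))
  cn <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  g <- mk_gcn(cn, c(s1 = 10, s2 = 20))
  expect_equal(copy_number_matrix(g), cn)
})

test_that("prevalence counts the 0.3-3 window among marker-eligible samples", {
  cn <- matrix(c(0.5, 2.9, 3.1, 0.2, 1, 1, 1, 1), 2, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
  g <- mk_gcn(cn, setNames(rep(10, 4), sprintf("s%d", 1:4)))
  prev <- gene_prevalence(g)
  expect_equal(unname(prev), c(0.5, 1))
  # a sample with marker coverage 4 leaves the denominator
  g2 <- mk_gcn(cn, setNames(c(10, 10, 10, 4), sprintf("s%d", 1:4)))
  expect_equal(unname(gene_prevalence(g2)["g1"]), 2 / 3)
  # no eligible samples: undefined for every gene
  g3 <- mk_gcn(cn, setNames(rep(2, 4), sprintf("s%d", 1:4)))
  expect_true(all(is.na(gene_prevalence(g3))))
})

test_that("core-gene membership is inclusive at 90% prevalence", {
  cn <- matrix(1, 2, 10, dimnames = list(c("g1", "g2"), sprintf("s%d", 1:10)))
  cn[1, 10] <- 0.1   # g1 prevalence 0.9, g2 prevalence 1
  cn2 <- cn; cn2[2, 9:10] <- 0.1  # g2 prevalence 0.8
  m <- setNames(rep(10, 10), colnames(cn))
  expect_setequal(core_genes(mk_gcn(cn, m)), c("g1", "g2"))
  expect_identical(core_genes(mk_gcn(cn2, m)), "g1")
  empty <- gene_cn_matrix("spX", matrix(0, 0, 2,
                                        dimnames = list(NULL, c("s1", "s2"))),
                          c(10, 10))
  expect_identical(core_genes(empty), character())
})

test_that("genes reaching copy number 3 anywhere are excluded", {
  cn <- matrix(c(1, 1, 3.2, 1, 2.9, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), sprintf("s%d", 1:3)))
  g <- mk_gcn(cn, setNames(rep(10, 3), colnames(cn)))
  expect_identical(high_copy_exclusions(g), "g1")
})

test_that("presence calls partition at the printed cutoffs", {
  cn <- matrix(c(0.04, 0.05, 0.06, 0.3, 0.6, 0.7, 1.2, 1.3), 8, 1,
               dimnames = list(sprintf("g%d", 1:8), "s1"))
  g25 <- mk_gcn(cn, c(s1 = 25))
  st <- call_presence(g25)[, 1]
  expect_identical(unname(st),
                   c("absent", "absent", "ambiguous", "ambiguous",
                     "present", "present", "present", "ambiguous"))
  # present demands marker coverage >= 20
  g15 <- mk_gcn(cn, c(s1 = 15))
  st15 <- call_presence(g15)[, 1]
  expect_identical(unname(st15["g6"]), "ambiguous")
  expect_identical(unname(st15["g1"]), "absent")   # absent still callable at 15x
  # below the minimal calling floor everything is ambiguous
  g4 <- mk_gcn(cn, c(s1 = 4))
  expect_true(all(call_presence(g4) == "ambiguous"))
  # partition: every cell is exactly one state
  expect_true(all(call_presence(g25) %in% c("present", "absent", "ambiguous")))
})

test_that("gain/loss counting excludes ambiguous endpoints", {
  t1 <- c(g1 = "present", g2 = "absent", g3 = "present", g4 = "ambiguous")
  t2 <- c(g1 = "absent", g2 = "present", g3 = "present", g4 = "present")
  r <- count_gains_losses(t1, t2)
  expect_equal(r$n_lost, 1)
  expect_equal(r$n_gained, 1)
  expect_equal(r$n_assayed, 3)
  # identity and swap symmetry
  expect_equal(unlist(count_gains_losses(t1, t1)[c("n_gained", "n_lost")]),
               c(n_gained = 0, n_lost = 0))
  rr <- count_gains_losses(t2, t1)
  expect_equal(rr$n_gained, r$n_lost)
  expect_equal(rr$n_lost, r$n_gained)
})

test_that("planted gene events are recovered from simulated time series", {
  prm <- sim_params(n_hosts = 10, n_focal_species = 2, base_strain_logit = -20,
                    base_loss_rate = 3e-4, base_gain_rate = 1e-4, seed = 19)
  sim <- simulate_cohort(prm)
  tb <- sim$tables
  tp <- fp <- fn <- 0
  for (sp in names(tb$genes)) {
    gcn <- tb$genes[[sp]]
    genes <- setdiff(rownames(gcn$coverage), high_copy_exclusions(gcn))
    st <- call_presence(gcn, genes = genes)
    ct <- sim$truth$gene_content[[sp]][genes, , drop = FALSE]
    for (h in unique(tb$samples$host_id)) {
      ss <- tb$samples$sample_id[tb$samples$host_id == h]
      if (min(gcn$marker_median[ss]) < 20) next
      called <- (st[, ss[1]] == "present" & st[, ss[2]] == "absent") |
        (st[, ss[1]] == "absent" & st[, ss[2]] == "present")
      truth <- (ct[, ss[1]] == 1 & ct[, ss[2]] == 0) |
        (ct[, ss[1]] == 0 & ct[, ss[2]] == 1)
      tp <- tp + sum(called & truth)
      fp <- fp + sum(called & !truth)
      fn <- fn + sum(!called & truth)
    }
  }
  expect_gt(tp, 10)               # events were actually planted
  expect_gte(tp / (tp + fp), 0.95)
  expect_gte(tp / (tp + fn), 0.95)
})

test_that("stable simulations produce almost no false events", {
  sim <- simulate_cohort(sim_params(n_hosts = 10, n_focal_species = 2,
                                    base_loss_rate = 0, base_gain_rate = 0,
                                    seed = 23))
  gl <- gain_loss_table(sim$tables, run_config())
  mm <- vapply(seq_len(nrow(gl)), function(i)
    min(sim$tables$genes[[gl$species_id[i]]]$marker_median[c(gl$t1[i], gl$t2[i])]),
    numeric(1))
  deep <- mm >= 30
  expect_gt(sum(deep), 0)
  expect_lt(mean(gl$n_gained[deep] + gl$n_lost[deep]), 0.5)
})
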