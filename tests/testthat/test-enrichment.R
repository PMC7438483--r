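test_that("fisher_exact_2x2 matches closed forms and enumeration", {
  # modal table (odds ratio 1): p = 1
  expect_equal(fisher_exact_2x2(matrix(c(10, 90, 100, 900), 2, byrow = TRUE)), 1)
  # perfectly discordant table: p = 2 / C(20,10)
  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 10, 0), 2, byrow = TRUE)),
               2 / choose(20, 10), tolerance = 1e-12)
  # brute-force check against stats::fisher.test over random tables
  set.seed(8)
  for (i in 1:200) {
    tab <- matrix(rpois(4, lambda = sample(c(3, 10, 40), 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("bh_fdr equals the literal step-up rule", {
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-15)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-15)
    # monotone: larger p never yields smaller q
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0,1")
})

enrich_fixture <- function(freq_target, freq_others, n_per_pop = 250,
                           n_snps = 6, seed = 2) {
  set.seed(seed)
  pops <- c("IR", "EUR", "AFR")
  fmat <- matrix(freq_others, n_snps, 3, dimnames = list(NULL, pops))
  fmat[, "IR"] <- freq_target
  D <- do.call(rbind, lapply(pops, function(p)
    sapply(seq_len(n_snps), function(j) rbinom(n_per_pop, 2, fmat[j, p]))))
  gm <- make_gm(D, populations = rep(pops, each = n_per_pop))
  cat <- harmonize(data.frame(
    snp_id = gm$variants$snp_id, chr = "1", pos = gm$variants$pos,
    effect_allele = "G", other_allele = "A", or = 1.3, pvalue = 1e-10,
    strand = "forward", gene = rep(c("GENE1", "GENE2"), length.out = n_snps),
    stringsAsFactors = FALSE))
  list(gm = gm, cat = cat, freqs = allele_frequencies(gm, cat))
}

test_that("test_enrichment flags direction, significance and conservation", {
  fx <- enrich_fixture(freq_target = 0.8, freq_others = 0.4)
  res <- test_enrichment(fx$cat, fx$freqs, alpha = 0.05)
  ir <- res[res$population == "IR", ]
  expect_true(all(ir$direction == "enriched"))
  expect_true(all(ir$qvalue < 0.05))
  expect_true(all(ir$significant))
  expect_true(all(ir$signed_score > 0))
  # depleted populations get negative signed scores
  other <- res[res$population != "IR" & res$significant, ]
  expect_true(all(other$direction == "depleted"))
  expect_true(all(other$signed_score < 0))
  # q >= p always; conservation of pooled counts
  expect_true(all(res$qvalue >= res$pvalue - 1e-15))
  expect_true(all(res$pop_risk + res$pop_nonrisk <=
                    res$glob_risk + res$glob_nonrisk))
  one <- res[res$snp_id == res$snp_id[1], ]
  expect_equal(unique(one$glob_risk), sum(one$pop_risk))
  # Fisher p on the constructed table matches the module's own test
  expect_equal(ir$pvalue[1],
               fisher_exact_2x2(matrix(c(ir$pop_risk[1], ir$pop_nonrisk[1],
                                         ir$glob_risk[1], ir$glob_nonrisk[1]),
                                       2, 2, byrow = TRUE)))
})

test_that("homogeneous populations are not significant (null case)", {
  fx <- enrich_fixture(freq_target = 0.4, freq_others = 0.4, seed = 5)
  res <- test_enrichment(fx$cat, fx$freqs, alpha = 0.05)
  expect_true(mean(res$significant) <= 0.05)
})

test_that("gene_level_counts equals a brute-force group-by", {
  fx <- enrich_fixture(freq_target = 0.8, freq_others = 0.4, n_snps = 10)
  res <- test_enrichment(fx$cat, fx$freqs)
  gc <- gene_level_counts(res)
  sig <- res[res$significant, ]
  for (k in seq_len(nrow(gc))) {
    expect_equal(gc$n_snps[k],
                 sum(sig$population == gc$population[k] &
                       sig$direction == gc$direction[k] &
                       sig$gene == gc$gene[k]))
  }
  # no significant results -> empty ranking
  fx0 <- enrich_fixture(freq_target = 0.4, freq_others = 0.4, seed = 6)
  res0 <- test_enrichment(fx0$cat, fx0$freqs)
  res0$significant <- FALSE
  expect_equal(nrow(gene_level_counts(res0)), 0L)
})

test_that("heatmap_matrix recovers planted opposite-direction groups", {
  cfg <- sim_config(n_snps = 60, n_catalog_snps = 60, n_risk_snps = 40,
                    ld_block_size = 1, or_range = c(1.3, 1.5),
                    populations = list(population_spec("AFR", 250, 0.02),
                                       population_spec("EAS", 250, 0.02),
                                       population_spec("EUR", 250, 0.02),
                                       population_spec("IR", 250, 0.02)),
                    seed = 23)
  fr <- simulate_frequency_table(cfg)
  gm0 <- simulate_genotypes(fr$pop_freqs, cfg)
  gwas <- simulate_gwas_table(gm0$variants, cfg)
  risk_rows <- which(attr(gwas, "risk_weights") > 0)
  ga <- risk_rows[1:15]; gb <- risk_rows[16:30]
  pf <- plant_enrichment_groups(fr$pop_freqs, ga, gb, delta = 0.25)
  gm <- simulate_genotypes(pf, cfg)
  cat <- harmonize(gwas)
  res_all <- test_enrichment(cat, allele_frequencies(gm, cat))
  ids_a <- gm$variants$snp_id[ga]
  ids_b <- gm$variants$snp_id[gb]
  res <- res_all[res_all$snp_id %in% c(ids_a, ids_b), ]
  hm <- heatmap_matrix(res)
  cl_a <- unique(hm$clusters[names(hm$clusters) %in% ids_a])
  cl_b <- unique(hm$clusters[names(hm$clusters) %in% ids_b])
  expect_length(cl_a, 1)
  expect_length(cl_b, 1)
  expect_false(cl_a == cl_b)
  # permuting input rows leaves the merge heights unchanged
  perm <- res[sample(nrow(res)), ]
  hm2 <- heatmap_matrix(perm)
  expect_equal(sort(hm2$hclust$height), sort(hm$hclust$height))
  # single significant SNP: trivial order
  one <- res[res$snp_id == res$snp_id[1], ]
  if (any(one$significant)) {
    hm1 <- heatmap_matrix(one)
    expect_equal(nrow(hm1$matrix), 1L)
  }
  res0 <- res
  res0$significant <- FALSE
  expect_error(heatmap_matrix(res0), "no significant")
})
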