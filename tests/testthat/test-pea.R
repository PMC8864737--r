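test_that("pmf and tails agree with the exact combinatorial oracle", {
  # frozen exact values: P(K=0 | M=20, n=4, N=10) = 14/323, and by the
  # symmetry of the distribution P(K>=4) at the same parameters is equal
  expect_equal(hypergeom_pmf(20, 4, 10, 0), 14 / 323, tolerance = 1e-14)
  expect_equal(enrichment_pvalue(20, 4, 10, 4), 14 / 323, tolerance = 1e-14)
  expect_equal(depletion_pvalue(20, 4, 10, 0), 14 / 323, tolerance = 1e-14)

  for (M in c(6L, 11L, 17L, 23L, 30L)) {
    for (n in c(0L, 1L, M %/% 3L, M %/% 2L, M)) {
      for (N in c(0L, 1L, M %/% 4L, M %/% 2L, M)) {
        v <- oracle_pmf_vector(M, n, N)
        ks <- 0:min(n, N)
        expect_equal(hypergeom_pmf(M, n, N, ks), v, tolerance = 1e-12)
        expect_equal(sum(v), 1, tolerance = 1e-12)
        for (k in ks) {
          expect_equal(enrichment_pvalue(M, n, N, k), oracle_p_enrich(M, n, N, k),
                       tolerance = 1e-12)
          expect_equal(depletion_pvalue(M, n, N, k), oracle_p_deplete(M, n, N, k),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("support boundaries and argument domains behave", {
  expect_equal(hypergeom_pmf(20, 4, 10, 11), 0)  # outside support, not an error
  expect_equal(hypergeom_pmf(20, 20, 10, 10), 1)  # M = n: all draws succeed
  expect_equal(enrichment_pvalue(20, 4, 10, 0), 1)
  expect_equal(depletion_pvalue(20, 4, 10, 4), 1)
  expect_equal(enrichment_pvalue(1314, 10, 1314, 10), 1)  # forced intersection
  expect_error(hypergeom_pmf(10, 11, 5, 1), class = "wp_domain_error")
  expect_error(hypergeom_pmf(10, 5, 11, 1), class = "wp_domain_error")
  expect_error(hypergeom_pmf(-1, 0, 0, 0), class = "wp_domain_error")
})

test_that("p_enrich is non-increasing in k at fixed (M, n, N)", {
  for (par in list(c(30, 10, 12), c(100, 25, 40), c(1314, 85, 200))) {
    ks <- 0:min(par[2], par[3])
    p <- enrichment_pvalue(par[1], par[2], par[3], ks)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("bonferroni_threshold is alpha over the number of tests", {
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 85), 0.05 / 85)
  expect_error(bonferroni_threshold(0, 10), class = "wp_domain_error")
  expect_error(bonferroni_threshold(0.05, 0), class = "wp_domain_error")
})

test_that("compute_overlap trims, deduplicates and reports unmatched tokens", {
  uni <- c("acdh-1", "pck-1", "pck-2")
  ov <- compute_overlap(c(" acdh-1", "acdh-1", "notagene"), uni)
  expect_equal(ov$hits, "acdh-1")
  expect_equal(ov$N, 1L)
  expect_equal(ov$unmatched, "notagene")
  expect_equal(ov$M, 3L)

  expect_equal(compute_overlap(uni, uni)$N, 3L)           # raw = universe
  expect_equal(compute_overlap(character(0), uni)$N, 0L)  # empty is valid

  # alias expansion only when a lookup table is supplied
  al <- c(ACDH1 = "acdh-1")
  expect_equal(compute_overlap("ACDH1", uni)$N, 0L)
  expect_equal(compute_overlap("ACDH1", uni, aliases = al)$hits, "acdh-1")
})

test_that("run_pea recovers the planted category and keeps raw p-values", {
  fx <- toy_fixture()
  pe <- generate_pea_input(fx$spec, fx$dir)
  raw <- readLines(pe$file)
  tab <- run_pea(raw[!startsWith(raw, "#")], fx$aset, levels = 4)
  expect_s3_class(tab, "pea_table")
  expect_equal(tab$input$N, pe$expected$N)
  expect_equal(tab$input$M, pe$expected$M)

  top <- tab$results[1, ]  # sorted by p_enrich within level
  expect_identical(top$category, pe$expected$category)
  expect_equal(top$k, pe$expected$k)
  expect_equal(top$n, pe$expected$n)
  expect_equal(top$score, 1)
  # exact tail from the oracle at fixture scale is the reference here
  expect_equal(top$p_enrich,
               stats::phyper(top$k - 1, top$n, tab$input$M - top$n,
                             tab$input$N, lower.tail = FALSE),
               tolerance = 1e-12)

  # tail identity on every emitted row
  for (i in seq_len(nrow(tab$results))) {
    r <- tab$results[i, ]
    expect_equal(r$p_enrich + r$p_deplete,
                 1 + hypergeom_pmf(tab$input$M, r$n, tab$input$N, r$k),
                 tolerance = 1e-12)
  }

  # stored values carry no multiple-testing correction: the advisory
  # Bonferroni cut-off lives only in summary()
  sm <- summary(tab)
  expect_equal(sm$bonferroni_threshold,
               0.05 / fx$spec$n_categories[4])
})

test_that("degenerate inputs force the analytic extremes", {
  fx <- toy_fixture()
  tab0 <- run_pea(character(0), fx$aset)
  expect_true(all(tab0$results$k == 0))
  expect_true(all(tab0$results$score == 0))
  expect_true(all(tab0$results$p_enrich == 1))

  tabM <- run_pea(fx$aset$universe, fx$aset)
  expect_true(all(tabM$results$k == tabM$results$n))
  expect_true(all(tabM$results$score == 1))
  expect_true(all(tabM$results$p_enrich == 1))
  expect_true(all(tabM$results$p_deplete == 1))
})

test_that("PEA outputs round-trip through the TSV and the HTML is well-formed", {
  fx <- toy_fixture()
  pe <- generate_pea_input(fx$spec, fx$dir)
  tab <- run_pea(read_gene_list(pe$file), fx$aset)
  out <- tempfile("peaout")
  files <- write_pea_outputs(tab, out)
  expect_true(all(file.exists(files)))

  back <- utils::read.delim(files[["tsv"]], stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(tab$results))
  expect_equal(back$level, tab$results$level)
  expect_equal(back$category, tab$results$category)
  expect_equal(back$k, tab$results$k)
  expect_equal(as.numeric(back$p_enrich), tab$results$p_enrich,
               tolerance = 1e-4)
  # deterministic row order: level asc, then p_enrich asc, then name
  expect_false(is.unsorted(back$level))
  for (lev in unique(back$level)) {
    expect_false(is.unsorted(back$p_enrich[back$level == lev]))
  }

  expect_silent(xml2::read_xml(files[["html"]]))
})

test_that("gene list files skip comments and blank lines", {
  path <- tempfile()
  writeLines(c("# comment", "acdh-1", "", "  pck-1  "), path)
  expect_equal(read_gene_list(path), c("acdh-1", "pck-1"))
})
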