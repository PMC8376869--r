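# Allele validation from amplicon tallies.

test_that("MPAF is the maximum within-amplicon frequency", {
  amp <- dplyr::bind_rows(
    amp_tbl("s1", 1, c("AAA", "CCC", "GGG"), c(60, 30, 10)),
    amp_tbl("s2", 1, c("AAA", "CCC"), c(2, 98)))
  rec <- tally_and_mpaf(amp)
  expect_equal(rec$mpaf[rec$sequence == "AAA"], 0.6)
  expect_equal(rec$mpaf[rec$sequence == "CCC"], 0.98)
  expect_equal(rec$mpaf[rec$sequence == "GGG"], 0.1)
  # a variant absent from all amplicons is never emitted
  expect_false("TTT" %in% rec$sequence)
  # empty amplicon rejected with its id
  expect_error(tally_and_mpaf(amp_tbl("s3", 1, "AAA", 0)), "s3")
})

test_that("prefilter flags frameshifts and global singletons", {
  amp <- dplyr::bind_rows(
    amp_tbl("s1", 1, c("AAATTTGGG", "AAATTTGG", "AAATTT", "CCCTTTGGG"),
            c(500, 40, 30, 1)))
  rec <- prefilter_variants(tally_and_mpaf(amp), ref_length = 9)
  get <- function(sq, col) rec[[col]][rec$sequence == sq]
  expect_true(get("AAATTTGG", "frameshift_indel"))     # 1 nt short
  expect_false(get("AAATTT", "frameshift_indel"))      # 3 nt short
  expect_true(get("CCCTTTGGG", "global_singleton"))    # one read overall
  expect_false(get("AAATTTGGG", "global_singleton"))
})

test_that("substitution-artifact rule needs distance 1 and higher freq", {
  amp <- amp_tbl("s1", 1, c("AAAA", "AAAT", "AATT", "CCCC"),
                 c(60, 1, 2, 37))
  expect_true(classify_substitution_artifact("AAAT", amp))   # d1 to AAAA
  expect_false(classify_substitution_artifact("CCCC", amp))  # d >= 2 to all
  # parent at lower frequency does not explain
  amp2 <- amp_tbl("s1", 1, c("AAAA", "AAAT"), c(1, 99))
  expect_false(classify_substitution_artifact("AAAT", amp2))
  # ties do not explain
  amp3 <- amp_tbl("s1", 1, c("AAAA", "AAAT"), c(50, 50))
  expect_false(classify_substitution_artifact("AAAT", amp3))
})

test_that("chimera classification matches the exhaustive oracle", {
  p1 <- "AAAAACCCCC"; p2 <- "GGGGGTTTTT"
  chim <- paste0(substr(p1, 1, 4), substr(p2, 5, 10))
  amp <- amp_tbl("s1", 1, c(p1, p2, chim), c(450, 430, 20))
  res <- classify_chimera(chim, amp)
  expect_true(res$is_chimera)
  expect_true(res$breakpoint >= 1 && res$breakpoint <= 9)
  expect_identical(paste0(substr(res$parent1, 1, res$breakpoint),
                          substr(res$parent2, res$breakpoint + 1, 10)),
                   chim)
  # identical to a parent: not a chimera
  expect_false(classify_chimera(p1, amp_tbl(
    "s1", 1, c(p1, p2, "AAAAATTTTT"), c(5, 400, 400)))$is_chimera)
  # one parent below the variant's own frequency: not explained
  amp_low <- amp_tbl("s1", 1, c(p1, p2, chim), c(450, 10, 20))
  expect_false(classify_chimera(chim, amp_low)$is_chimera)

  # property: agreement with exhaustive breakpoint enumeration on fuzzed
  # amplicons
  withr::with_seed(99, {
    for (rep in 1:25) {
      L <- 12
      seqs <- unique(vapply(1:5, function(i) {
        paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      }, character(1)))
      reads <- sample(1:500, length(seqs), TRUE)
      amp <- amp_tbl("s", 1, seqs, reads)
      for (sq in seqs) {
        expect_identical(classify_chimera(sq, amp)$is_chimera,
                         chimera_oracle(sq, amp))
      }
    }
  })
})

test_that("validate_alleles applies the rule hierarchy", {
  true1 <- "AAAAAACCCCCC"; true2 <- "GGGGGGTTTTTT"
  err1 <- "AAAAATCCCCCC"                       # 1-bp derivative of true1
  chim <- paste0(substr(true1, 1, 6), substr(true2, 7, 12))
  novel <- "CACACACACACA"                      # real low-frequency allele
  amp <- dplyr::bind_rows(
    amp_tbl("s1", 1, c(true1, true2, err1, chim),
            c(2000, 1800, 40, 60)),
    amp_tbl("s1", 2, c(true1, true2), c(1500, 1400)),
    amp_tbl("s2", 1, c(true1, novel), c(2900, 100)))
  out <- validate_alleles(amp, mpaf_threshold = 0.05,
                          roster = c("s1", "s2", "s3"))
  expect_setequal(out$alleles$sequence, c(true1, true2, novel))
  st <- function(sq) out$variants$status[out$variants$sequence == sq]
  expect_equal(st(err1), "artifact")
  expect_equal(st(chim), "artifact")
  expect_equal(st(novel), "true_allele")
  expect_setequal(out$no_amplification, "s3")
  # genotype = union of true alleles over replicates
  g1 <- out$genotypes$allele[out$genotypes$specimen == "s1"]
  expect_setequal(unique(g1), c(true1, true2))

  # a frameshift variant is an artifact regardless of MPAF
  amp_fs <- dplyr::bind_rows(
    amp_tbl("s1", 1, c(true1, substr(true1, 1, 11)), c(900, 100)))
  out_fs <- validate_alleles(amp_fs, mpaf_threshold = 0.05)
  expect_equal(out_fs$variants$status[
    out_fs$variants$sequence == substr(true1, 1, 11)], "artifact")
})

test_that("clean simulated data is recovered exactly and idempotently", {
  cfg <- small_config(seed = 13, substitution_rate = 0, chimera_rate = 0,
                      no_amplification_rate = 0)
  st <- simulate_mhc_study(cfg)
  out <- validate_alleles(st$amplicons$amplicons)
  carried <- unique(st$genotypes$allele)
  carried_seq <- st$pools$sequence[st$pools$allele %in% carried]
  expect_setequal(out$alleles$sequence, carried_seq)

  # idempotence: re-validating the accepted read set returns the same set
  clean <- st$amplicons$amplicons[
    st$amplicons$amplicons$sequence %in% out$alleles$sequence, ]
  out2 <- validate_alleles(clean)
  expect_setequal(out2$alleles$sequence, out$alleles$sequence)
})

test_that("every variant gets exactly one status and the threshold is monotone", {
  cfg <- small_config(seed = 14)
  st <- simulate_mhc_study(cfg)
  out_lo <- validate_alleles(st$amplicons$amplicons,
                             mpaf_threshold = 0.03)
  expect_true(all(out_lo$variants$status %in%
                    c("true_allele", "artifact")))
  out_hi <- validate_alleles(st$amplicons$amplicons,
                             mpaf_threshold = 0.08)
  # raising the threshold never converts an artifact into a true allele
  was_artifact <- out_lo$variants$sequence[
    out_lo$variants$status == "artifact"]
  now_true <- out_hi$variants$sequence[
    out_hi$variants$status == "true_allele"]
  expect_length(intersect(was_artifact, now_true), 0)
})

test_that("replicate concordance reports Jaccard agreement", {
  g <- tibble::tibble(
    specimen = c("a", "a", "a", "a", "b", "b", "c"),
    replicate = c(1, 1, 2, 2, 1, 2, 1),
    allele = c("x", "y", "x", "y", "x", "y", "x"))
  out <- replicate_concordance(g)
  expect_equal(out$concordance[out$specimen == "a"], 1)
  expect_equal(out$concordance[out$specimen == "b"], 0)
  expect_true(is.na(out$concordance[out$specimen == "c"]))
  expect_equal(out$n_replicates[out$specimen == "c"], 1)
  expect_true(out$flagged[out$specimen == "b"])
})

test_that("lineage assignment recovers pool labels from exemplars", {
  # exact exemplar match
  out <- assign_lineage(c(a = "AAAA"), c(e1 = "AAAA", e2 = "TTTT"),
                        c("DAB1", "DAB3"))
  expect_equal(out$lineage, "DAB1")
  # equidistant: unresolved
  tie <- assign_lineage(c(a = "AATT"), c(e1 = "AAAA", e2 = "TTTT"),
                        c("DAB1", "DAB3"))
  expect_equal(tie$lineage, "unresolved")

  # synthetic pools: exemplar = one allele per lineage, full recovery
  cfg <- small_config(seed = 15)
  pools <- simulate_allele_pools(cfg)
  ex <- dplyr::slice_head(dplyr::group_by(pools, lineage), n = 1)
  out <- assign_lineage(
    stats::setNames(pools$sequence, pools$allele),
    stats::setNames(ex$sequence, ex$allele), ex$lineage)
  expect_equal(out$lineage, pools$lineage)
  expect_error(assign_lineage(c(a = "AAAA"), character(0), character(0)),
               "exemplar")
})
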