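test_that("biochemical state machine reproduces the FCP boundaries", {
  cases <- rbind(
    data.frame(fcp = 250,    state = "ACTIVE"),        # >= 250 is active
    data.frame(fcp = 99.9,   state = "REMISSION"),     # < 100 is remission
    data.frame(fcp = 150,    state = "INDETERMINATE"), # [100, 250) gap
    data.frame(fcp = 0,      state = "REMISSION"),
    data.frame(fcp = 100,    state = "INDETERMINATE"),
    data.frame(fcp = 249.99, state = "INDETERMINATE"),
    data.frame(fcp = 1000,   state = "ACTIVE"))
  expect_equal(classifyBiochemical(cases$fcp), cases$state)
  expect_error(classifyBiochemical(NA_real_), "missing FCP")
  expect_error(classifyBiochemical(-1), "negative")

  # monotone step function in severity as FCP increases
  sev <- match(classifyBiochemical(seq(0, 600, by = 2.5)),
               c("REMISSION", "INDETERMINATE", "ACTIVE"))
  expect_true(all(diff(sev) >= 0))

  # thresholds are configuration: a 200 mg/g active cut-off
  th <- stateThresholds(fcpActive = 200)
  expect_equal(classifyBiochemical(210, th), "ACTIVE")
})

test_that("clinical state machine covers HBI and SCCAI with the HBI gap", {
  expect_equal(classifyClinical("CD", hbi = 5), "ACTIVE")
  expect_equal(classifyClinical("CD", hbi = 3), "REMISSION")
  expect_equal(classifyClinical("CD", hbi = 4), "INDETERMINATE")
  expect_equal(classifyClinical("UC", sccai = 3), "ACTIVE")
  expect_equal(classifyClinical("UC", sccai = 2), "REMISSION")
  expect_equal(classifyClinical("IBDU", sccai = 0), "REMISSION")
  # SCCAI has no definitional gap: every value is determinate
  expect_true(all(classifyClinical(rep("UC", 20), sccai = 0:19) %in%
                    c("REMISSION", "ACTIVE")))
  expect_error(classifyClinical("CD"), "missing")
  expect_error(classifyClinical("UC", hbi = 5, sccai = 2), "inconsistent")
})

test_that("pairing assembles consecutive same-patient transitions", {
  rec <- function(pid, fcps) data.frame(
    patient_id = pid, sample_id = paste0(pid, "_", seq_along(fcps)),
    seq_index = seq_along(fcps), fcp = fcps, hbi = NA_integer_,
    sccai = NA_integer_, subtype = "CD", stringsAsFactors = FALSE)

  # remission then exacerbation: one B2 pair
  p <- pairSamples(rec("P1", c(50, 300)), "BIOCHEMICAL")
  expect_equal(p$group, "B2")
  expect_equal(p$first_sample_id, "P1_1")

  # a middle sample closes one pair and opens the next
  p <- pairSamples(rec("P2", c(300, 260, 80)), "BIOCHEMICAL")
  expect_equal(p$group, c("B3", "B4"))

  # an indeterminate second sample drops the pair, with a logged reason
  p <- pairSamples(rec("P3", c(50, 150)), "BIOCHEMICAL")
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "dropped")$reason, "indeterminate state")

  # missing FCP cannot be labelled biochemically; logged, not raised
  r <- rec("P4", c(50, NA))
  p <- pairSamples(r, "BIOCHEMICAL")
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "dropped")$reason, "missing score")

  # pairs never cross patients and are always seq-adjacent
  set.seed(15)
  recs <- do.call(rbind, lapply(1:8, function(i)
    rec(paste0("Q", i), runif(sample(2:5, 1), 0, 600))))
  pp <- pairSamples(recs, "BIOCHEMICAL")
  if (nrow(pp)) {
    i1 <- as.integer(sub(".*_", "", pp$first_sample_id))
    i2 <- as.integer(sub(".*_", "", pp$second_sample_id))
    expect_true(all(i2 - i1 == 1))
    expect_true(all(sub("_.*", "", pp$first_sample_id) == pp$patient_id))
  }

  # labelling purity: identical input, identical output
  expect_identical(pairSamples(recs, "BIOCHEMICAL"),
                   pairSamples(recs, "BIOCHEMICAL"))
})

test_that("group counts report every code, including zeros", {
  empty <- pairSamples(data.frame(patient_id = character(0),
                                  sample_id = character(0),
                                  seq_index = integer(0), fcp = numeric(0),
                                  hbi = integer(0), sccai = integer(0),
                                  subtype = character(0)), "BIOCHEMICAL")
  expect_equal(unname(groupCounts(empty)), rep(0L, 8))
  md <- rbind(simulateMetadata("B3", 4, prefix = "a"),
              simulateMetadata("B1", 2, prefix = "b"))
  counts <- groupCounts(pairSamples(md, "BIOCHEMICAL"))
  expect_equal(counts[["B3"]], 4)
  expect_equal(counts[["B1"]], 2)
  expect_equal(counts[["B2"]], 0)  # absent codes are 0, not omitted
  expect_equal(names(counts),
               c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4"))
})
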