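test_that("the packaged character matrix parses with states and ranges", {
  m <- trait_fixture()
  expect_equal(length(m$species), 78)
  expect_equal(m$species[1], "B. lushanensis")
  expect_equal(unname(m$svl_male_mm["B. lushanensis", ]), c(40.5, 44.7))
  st <- m$states
  expect_equal(st$vomerine_teeth[["B. lushanensis"]], "T")
  expect_equal(st$heels[["B. lushanensis"]], "F")
  expect_equal(st$toe_fringes[["B. lushanensis"]], "N")
  expect_equal(st$eyelid_tubercle_large[["B. jinggangensis"]], "T")
  expect_equal(st$heels[["B. jinggangensis"]], "T")
  # polymorphic and missing cells
  expect_setequal(st$heels[["B. angka"]], c("T", "N"))
  expect_length(st$heels[["B. shuichengensis"]], 0)
  expect_true(any(m$parse_report$kind == "polymorphic"))
  # spacing and alias normalization
  expect_true("B. hengshanensis" %in% m$species)
  expect_equal(trait_state <- m$states$vomerine_teeth[["B. huangnniushienensis"]],
               "F")
})

test_that("unknown state symbols are rejected with the offending cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("species", "svl_male_mm", "svl_female_mm",
                     "eyelid_tubercle_large", "vomerine_teeth",
                     "tongue_notched", "heels", "toe_fringes",
                     "toe_webbing", sep = "\t"),
               "B. demo\t30-31\t/\tF\tQ\tF\tT\tN\tN"), path)
  expect_error(load_trait_matrix(path), "Q.*B\\. demo")
})

test_that("distinguishing characters require disjoint state sets", {
  m <- trait_fixture()
  d <- distinguishing_characters(m, "B. lushanensis", "B. jinggangensis")
  expect_setequal(d$character, c("svl_male_mm", "svl_female_mm",
                                 "eyelid_tubercle_large", "heels"))
  expect_equal(d$focal_state[d$character == "eyelid_tubercle_large"], "F")
  expect_equal(d$other_state[d$character == "eyelid_tubercle_large"], "T")
  expect_equal(d$focal_state[d$character == "heels"], "F")
  expect_equal(d$other_state[d$character == "heels"], "T")
  # self comparison: nothing distinguishes
  expect_equal(nrow(distinguishing_characters(m, "B. lushanensis",
                                              "B. lushanensis")), 0)
  # overlapping polymorphism is not diagnostic: daoji heels F vs angka {T,N}
  # is disjoint, but angka {T,N} vs jinggangensis {T} overlaps
  d2 <- distinguishing_characters(m, "B. angka", "B. jinggangensis")
  expect_false("heels" %in% d2$character)
  # overlapping SVL ranges are not diagnostic
  d3 <- distinguishing_characters(m, "B. lushanensis", "B. daxuemontis")
  expect_false("svl_male_mm" %in% d3$character)   # 40.5-44.7 vs 41.2-46.2
})

test_that("disjointness is symmetric across random species pairs", {
  m <- trait_fixture()
  set.seed(21)
  for (i in 1:25) {
    pair <- sample(m$species, 2)
    a <- distinguishing_characters(m, pair[1], pair[2])
    b <- distinguishing_characters(m, pair[2], pair[1])
    expect_setequal(a$character, b$character)
  }
})

test_that("state partitions are complete and match the published lists", {
  m <- trait_fixture()
  cl <- claims_fixture()
  part <- partition_by_state(m, "vomerine_teeth", "B. lushanensis")
  # every congener in exactly one bucket
  all_members <- unlist(part)
  expect_setequal(all_members, setdiff(m$species, "B. lushanensis"))
  expect_equal(anyDuplicated(all_members), 0)
  # the vomerine-absent bucket reproduces the published comparison list
  claimed <- vapply(cl$claims[[1]]$species, function(s)
    if (s %in% names(cl$aliases)) unname(cl$aliases[s]) else s, character(1))
  expect_setequal(part$F, claimed)
  # heels: three diagnostic buckets plus the not-distinguished remainder
  heels <- partition_by_state(m, "heels", "B. lushanensis")
  expect_setequal(names(heels), c("not_distinguished", "T", "N", "T/N"))
  all_heels <- unlist(heels)
  expect_setequal(all_heels, setdiff(m$species, "B. lushanensis"))
  expect_equal(anyDuplicated(all_heels), 0)
})

test_that("claims generated from the matrix itself audit clean", {
  m <- trait_fixture()
  part <- partition_by_state(m, "vomerine_teeth", "B. lushanensis")
  self_claims <- list(claims = list(list(
    character = "vomerine_teeth", claimed_state = "F",
    species = part$F)))
  expect_equal(nrow(audit_consistency(m, self_claims)), 0)
  expect_equal(nrow(audit_consistency(m, list(claims = list()))), 0)
})

test_that("the audit reports the published heel-placement discrepancies", {
  m <- trait_fixture()
  aud <- audit_consistency(m, claims_fixture())
  expect_s3_class(aud, "data.frame")
  expect_gt(nrow(aud), 0)
  fj <- aud[aud$species == "B. fanjingmontis" & aud$character == "heels", ]
  expect_equal(nrow(fj), 1)
  expect_equal(fj$table_state, "N")
  expect_equal(fj$claimed_state, "T")
  # no mismatch anywhere in the vomerine list
  expect_false(any(aud$character == "vomerine_teeth"))
})

test_that("the full diagnosis report covers every congener and character", {
  m <- trait_fixture()
  rep <- diagnosis_report(m, "B. lushanensis")
  expect_equal(rep$focal, "B. lushanensis")
  expect_length(rep$per_congener, 77)
  expect_length(rep$per_character, 6)
  # its closest relative is distinguished by at least one character
  expect_gt(nrow(rep$per_congener[["B. jinggangensis"]]), 0)
})
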