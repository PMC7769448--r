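simple_taxa <- function(names) resolve_names(names, make_synonyms(names))

test_that("the BIN index maps bins to public species across the whole store", {
  store <- make_store(c("Mola mola", "Mola mola", "Ranzania laevis",
                        "Thunnus obesus", "Thunnus obesus"),
                      bin = c("BOLD:AAA0001", "BOLD:AAA0001", "BOLD:AAA0001",
                              "BOLD:AAB0002", NA),
                      visibility = c(rep("public", 4), "public"))
  idx <- build_bin_index(store, simple_taxa(c("Mola mola", "Ranzania laevis",
                                              "Thunnus obesus")))
  expect_setequal(idx[["BOLD:AAA0001"]], c("Mola mola", "Ranzania laevis"))
  expect_equal(idx[["BOLD:AAB0002"]], "Thunnus obesus")
  expect_equal(attr(idx, "n_unbinned"), 1L)

  # private records never enter the index
  priv <- make_store("Mola mola", bin = "BOLD:AAA0001", visibility = "private")
  expect_length(build_bin_index(priv, simple_taxa("Mola mola")), 0)
  expect_length(build_bin_index(make_store(character(0))), 0)
})

test_that("each grading criterion is met by its canonical record set", {
  grade_of <- function(store, name = "Mola mola", min_barcodes = 3, ...) {
    taxa <- simple_taxa(unique(c(name, store$species_label)))
    idx <- build_bin_index(store, taxa)
    recs <- store[norm_label(store$species_label) == norm_label(name) &
                    store$visibility == "public", ]
    grade_species(name, recs, idx, min_barcodes = min_barcodes, ...)$grade
  }
  norm_label <- function(x) tolower(trimws(x))

  # four vouchered records, one exclusive BIN
  expect_equal(grade_of(make_store(rep("Mola mola", 4), bin = "BOLD:AAA0001")),
               "AB")
  # two records are data deficient regardless of BINs
  expect_equal(grade_of(make_store(rep("Mola mola", 2),
                                   bin = c("BOLD:AAA0001", "BOLD:AAB0002"))),
               "D")
  # split over two exclusive BINs
  expect_equal(grade_of(make_store(rep("Mola mola", 4),
                                   bin = c("BOLD:AAA0001", "BOLD:AAA0001",
                                           "BOLD:AAB0002", "BOLD:AAB0002"))),
               "C")
  # one BIN shared with another species
  expect_equal(grade_of(make_store(c(rep("Mola mola", 3), "Ranzania laevis"),
                                   bin = "BOLD:AAA0001")),
               "E*")
  # several BINs, one shared with another species
  expect_equal(grade_of(make_store(c(rep("Mola mola", 4), "Ranzania laevis"),
                                   bin = c("BOLD:AAA0001", "BOLD:AAA0001",
                                           "BOLD:AAB0002", "BOLD:AAB0002",
                                           "BOLD:AAB0002"))),
               "E**")
  # every record GenBank-mined: inadequate procedure beats everything
  expect_equal(grade_of(make_store(rep("Mola mola", 5), bin = "BOLD:AAA0001",
                                   mined = TRUE)),
               "F")
  # ... unless D-first is requested for sensitivity analysis
  expect_equal(grade_of(make_store(rep("Mola mola", 2), bin = "BOLD:AAA0001",
                                   mined = TRUE), f_precedence = FALSE),
               "D")
  # all unvouchered is the other route to F
  expect_equal(grade_of(make_store(rep("Mola mola", 4), bin = "BOLD:AAA0001",
                                   voucher = "unvouchered")),
               "F")
  # unknown voucher status is treated as vouchered (conservative for F)
  expect_equal(grade_of(make_store(rep("Mola mola", 4), bin = "BOLD:AAA0001",
                                   voucher = c("unvouchered", "unknown",
                                               "unvouchered", "unvouchered"))),
               "AB")
  # enough records but no BIN assignment at all
  expect_equal(grade_of(make_store(rep("Mola mola", 3))), "ungradable")
  # records without a BIN still count toward the deficiency threshold
  expect_equal(grade_of(make_store(rep("Mola mola", 4),
                                   bin = c("BOLD:AAA0001", NA, NA, NA))),
               "AB")
})

test_that("audit grades partition the public species and ignore record order", {
  for (seed in 1:5) {
    uni <- generate_universe(small_config(seed))
    res <- run_universe(uni)
    expect_equal(nrow(res$audit),
                 sum(res$summaries$availability == "public"))
    expect_true(all(res$audit$grade %in%
                      c("AB", "C", "D", "E*", "E**", "F", "ungradable")))
    shuffled <- uni$records[sample(nrow(uni$records)), ]
    res2 <- run_gap_analysis(uni$checklist, uni$synonyms,
                             as_barcode_store(shuffled), uni$region)
    expect_equal(res2$audit, res$audit)
  }
})

test_that("raising the deficiency threshold only ever moves species into D", {
  uni <- generate_universe(small_config(13))
  res3 <- run_universe(uni, min_barcodes = 3)
  res5 <- run_universe(uni, min_barcodes = 5)
  d3 <- res3$audit$valid_name[res3$audit$grade == "D"]
  d5 <- res5$audit$valid_name[res5$audit$grade == "D"]
  expect_true(all(d3 %in% d5))
  res1 <- run_universe(uni, min_barcodes = 1)
  d1 <- res1$audit$valid_name[res1$audit$grade == "D"]
  expect_length(d1, 0) # nothing is deficient at threshold 1
})

test_that("composition percentages per group sum to 100 and track counts", {
  audit <- tibble::tibble(
    valid_name = paste("Genus", letters[1:3]),
    taxon_group = "Actinopterygii",
    n_barcodes = 4L, n_bins = 1L,
    grade = c("AB", "AB", "D"),
    shared_bin_species = "")
  comp <- audit_composition(audit)
  expect_equal(comp$pct[comp$grade == "AB"], 66.7)
  expect_equal(comp$pct[comp$grade == "D"], 33.3)
  expect_equal(sum(comp$pct), 100)

  single <- audit_composition(audit[1, ])
  expect_equal(single$pct[single$grade == "AB"], 100)

  # taxonomic-uncertainty aggregate C + E* + E**; the sum-preserving rounding
  # gives the tie-broken extra 0.1 to the first grade (AB), so 33.3 + 33.3
  audit$grade <- c("C", "E*", "AB")
  comp2 <- audit_composition(audit)
  expect_equal(sum(comp2$pct), 100)
  unc <- attr(comp2, "uncertainty")
  expect_equal(unc$pct_uncertain, 66.6)
})

test_that("planted grade compositions are recovered exactly via quota counts", {
  mix <- c("AB" = 0.5, "C" = 0.2, "D" = 0.3, "E*" = 0, "E**" = 0, "F" = 0)
  cfg <- small_config(99, n_species_per_group = c(GroupA = 250),
                      barcode_coverage = 1, public_fraction = 0.8,
                      grade_mix = mix, nonbinomial_rate = 0)
  uni <- generate_universe(cfg)
  res <- run_universe(uni)
  expect_equal(nrow(res$audit), 200) # exact quota: 80% of 250 public
  got <- table(res$audit$grade)
  expect_equal(got[["AB"]], 100)
  expect_equal(got[["C"]], 40)
  expect_equal(got[["D"]], 60)
})

test_that("grading agrees with an independent criteria implementation", {
  for (seed in 20:25) {
    uni <- generate_universe(small_config(seed))
    res <- run_universe(uni)
    for (i in seq_len(nrow(res$audit))) {
      expect_equal(
        res$audit$grade[i],
        oracle_grade(res$audit$valid_name[i], uni$records, res$taxa),
        info = paste("seed", seed, res$audit$valid_name[i]))
    }
  }
})
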