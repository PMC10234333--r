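make_ref <- function(len = 800, seed = 17) {
  set.seed(seed)
  sequence_record("ref", random_dna(len))
}

test_that("signature profiles validate their positions", {
  expect_error(signature_profile(c(10, 5), c("A", "C"), "r"), "increasing")
  expect_error(signature_profile(c(5, 10), c("A", "Z"), "r"), "A, C, G or T")
  pr <- signature_profile(c(5, 10, 22), c("A", "C", "G"), "r")
  expect_equal(pr$n_positions, 3)
})

test_that("reference positions map through substitutions, indels, and truncation", {
  ref <- make_ref(400)
  pr <- signature_profile(c(50, 150, 300),
                          substring(ref$sequence, c(50, 150, 300),
                                    c(50, 150, 300)),
                          ref$id)
  # identity map on itself
  map <- map_reference_positions(ref, ref, pr)
  expect_equal(map$query_position, pr$positions)
  expect_true(all(map$covered))
  expect_equal(map$query_base, pr$expected_bases)

  # a single deletion upstream shifts downstream query positions by one
  qdel <- sequence_record("q", paste0(substr(ref$sequence, 1, 99),
                                      substr(ref$sequence, 101, 400)))
  mapd <- map_reference_positions(qdel, ref, pr)
  expect_equal(mapd$query_position[1], 50)    # upstream of the deletion
  expect_equal(mapd$query_position[2], 149)   # shifted by the deletion
  expect_equal(mapd$query_position[3], 299)
  expect_true(all(mapd$covered))

  # truncation leaves later positions uncovered
  qtr <- sequence_record("q2", substr(ref$sequence, 1, 200))
  mapt <- map_reference_positions(qtr, ref, pr)
  expect_equal(mapt$covered, c(TRUE, TRUE, FALSE))
})

test_that("the two-step screen classifies members, mismatches, and gaps strictly", {
  ref <- make_ref(800)
  pos <- sort(sample(setdiff(60:640, 0), 12))
  pr <- signature_profile(pos, substring(ref$sequence, pos, pos), ref$id)
  th <- screening_thresholds()

  # the reference against itself is a member with full identity
  v <- screen_sequence(ref, ref, pr, th)
  expect_equal(v$verdict, "member")
  expect_equal(v$identity_pct, 100)
  expect_equal(v$positions_matched, pr$n_positions)

  # three mismatches in the 601-base region: 99.50 % < 99.6 -> step-1 reject
  non_sig <- setdiff(60:640, pos)
  at3 <- sample(non_sig, 3)
  q995 <- sequence_record("q995", mutate_exact(ref$sequence, 3, at = at3))
  v995 <- screen_sequence(q995, ref, pr, th)
  expect_equal(v995$step1, "fail_identity")
  expect_equal(v995$verdict, "non_member")
  expect_lt(v995$identity_pct, 99.6)

  # a single mismatched signature base fails step 2 despite passing step 1
  q1 <- sequence_record("q1", mutate_exact(ref$sequence, 1, at = pos[5]))
  v1 <- screen_sequence(q1, ref, pr, th)
  expect_equal(v1$step1, "pass")
  expect_equal(v1$verdict, "non_member")
  expect_equal(v1$positions_matched, pr$n_positions - 1)

  # an ambiguity code at a signature position counts as uncovered
  chars <- strsplit(ref$sequence, "")[[1]]
  chars[pos[3]] <- "N"
  qamb <- sequence_record("qamb", paste(chars, collapse = ""))
  vamb <- screen_sequence(qamb, ref, pr, th)
  expect_equal(vamb$verdict, "not_classifiable")
  expect_equal(vamb$positions_covered, pr$n_positions - 1)

  # too short to classify at all
  vshort <- screen_sequence(sequence_record("s", substr(ref$sequence, 1, 150)),
                            ref, pr, th)
  expect_equal(vshort$verdict, "not_classifiable")

  # a query covering only part of the region fails coverage, not identity
  qpart <- sequence_record("qp", substr(ref$sequence, 1, 350))
  vpart <- screen_sequence(qpart, ref, pr, th)
  expect_equal(vpart$step1, "fail_coverage")
  expect_equal(vpart$verdict, "not_classifiable")
})

test_that("lowering the identity threshold never turns a member into a non-member", {
  ref <- make_ref(800, seed = 23)
  pos <- sort(sample(60:640, 10))
  pr <- signature_profile(pos, substring(ref$sequence, pos, pos), ref$id)
  set.seed(5)
  queries <- c(list(ref), lapply(1:5, function(i)
    sequence_record(paste0("q", i),
                    mutate_exact(ref$sequence, i,
                                 at = sample(setdiff(60:640, pos), i)))))
  strict <- vapply(queries, function(q)
    screen_sequence(q, ref, pr, screening_thresholds(99.6))$verdict, "")
  loose <- vapply(queries, function(q)
    screen_sequence(q, ref, pr, screening_thresholds(95))$verdict, "")
  was_member <- strict == "member"
  expect_true(all(loose[was_member] == "member"))
})

test_that("conservation/exclusivity evaluation reports the planted structure", {
  panel <- simulate_16s_panel(n_ingroup = 6, n_outgroup = 10, seed = 71)
  ev <- evaluate_signature_set(panel$ingroup, panel$outgroup,
                               panel$reference, panel$profile)
  expect_equal(ev$n_conserved, panel$profile$n_positions)
  expect_equal(ev$n_exclusive, 1)
  expect_equal(
    ev$per_position$reference_position[ev$per_position$exclusive],
    panel$truth$exclusive_position)
  expect_true(ev$combination_exclusive)

  # panel order does not matter
  ev2 <- evaluate_signature_set(rev(panel$ingroup), rev(panel$outgroup),
                                panel$reference, panel$profile)
  expect_equal(ev2$per_position, ev$per_position)

  # mutating one signature site in an in-group sequence breaks conservation
  broken <- panel$ingroup
  set.seed(3)
  broken[[1]] <- sequence_record(
    "broken", mutate_exact(broken[[1]]$sequence, 1,
                           at = panel$profile$positions[4]))
  ev3 <- evaluate_signature_set(broken, panel$outgroup, panel$reference,
                                panel$profile)
  expect_equal(ev3$n_conserved, panel$profile$n_positions - 1)
  expect_false(ev3$per_position$conserved_in_ingroup[4])
})

test_that("an out-group sequence with 36 of 37 states leaves the combination exclusive", {
  ref <- make_ref(800, seed = 29)
  pos <- sort(sample(60:640, 37))
  pr <- signature_profile(pos, substring(ref$sequence, pos, pos), ref$id)
  ing <- list(ref)
  set.seed(6)
  near_out <- sequence_record("o1", mutate_exact(ref$sequence, 1,
                                                 at = pos[20]))
  ev <- evaluate_signature_set(ing, list(near_out), ref, pr)
  expect_true(ev$combination_exclusive)
  expect_equal(ev$n_exclusive, 1)  # only the mutated position is exclusive
})

test_that("pairwise identity uses gap-inclusive global alignment columns", {
  set.seed(47)
  s <- random_dna(600)
  recs <- list(sequence_record("a", s), sequence_record("b", s),
               sequence_record("c", mutate_exact(s, 1)))
  m <- pairwise_identity_matrix(recs)
  expect_equal(m["a", "b"], 100)
  expect_equal(m["a", "c"], 100 * 599 / 600, tolerance = 1e-10)
  expect_equal(m, t(m))
})

test_that("signature profiles round-trip through the TSV format", {
  pr <- signature_profile(c(52, 224, 610), c("A", "G", "T"), "ref_16s",
                          "E. coli SSU numbering")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature_profile(pr, f)
  back <- read_signature_profile(f)
  expect_equal(back$positions, pr$positions)
  expect_equal(back$expected_bases, pr$expected_bases)
  expect_equal(back$reference_id, "ref_16s")
  expect_equal(back$numbering_scheme, "E. coli SSU numbering")
})
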