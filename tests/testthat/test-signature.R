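test_that("construct names parse into base id, stem length and suffix", {
  expect_equal(parse_variant_name("980_9"),
               list(base_id = "980", stem_length_bp = 9L,
                    variant_suffix = NA_character_))
  expect_equal(parse_variant_name("980"),
               list(base_id = "980", stem_length_bp = 11L,
                    variant_suffix = NA_character_))
  expect_equal(parse_variant_name("4LVV_9.1"),
               list(base_id = "4LVV", stem_length_bp = 9L,
                    variant_suffix = "1"))
  expect_error(parse_variant_name("980_12"), "_12")
  expect_error(parse_variant_name(""), "non-empty")
})

test_that("pair classification matches the enumerated truth table", {
  bases <- c("A", "C", "G", "U")
  truth <- matrix("MISMATCH", 4, 4, dimnames = list(bases, bases))
  truth["A", "U"] <- truth["U", "A"] <- "WATSON_CRICK"
  truth["G", "C"] <- truth["C", "G"] <- "WATSON_CRICK"
  truth["G", "U"] <- truth["U", "G"] <- "WOBBLE"
  for (a in bases) for (b in bases)
    expect_identical(classify_pair(a, b), truth[a, b])
  expect_identical(classify_pair("A", "-"), "UNPAIRED")
  expect_identical(classify_pair(NA, "G"), "UNPAIRED")
  expect_error(classify_pair("T", "A"), "non-RNA")
})

test_that("pairing profile reports the five long-range pairs and G:C count", {
  v <- make_variant_fixtures()
  p980 <- pairing_profile(v[["980"]])
  expect_equal(nrow(p980$pairs), 5L)
  expect_equal(p980$pairs$loop_pos, as.character(8:12))
  expect_equal(p980$pairs$receptor_pos, as.character(22:18))
  expect_equal(p980$pairs$class,
               c("WATSON_CRICK", "WATSON_CRICK", "WATSON_CRICK",
                 "MISMATCH", "WATSON_CRICK"))
  expect_equal(p980$gc_count, 3L)

  # 593 carries A10:U20 in place of 980's G10:C20 - still Watson-Crick
  p593 <- pairing_profile(v[["593"]])
  expect_identical(p593$pairs$class[p593$pairs$loop_pos == "10"],
                   "WATSON_CRICK")
  expect_equal(p593$gc_count, 2L)

  # 3SUX has the G9:U21 wobble
  p3sux <- pairing_profile(v[["3SUX"]])
  expect_identical(p3sux$pairs$class[p3sux$pairs$loop_pos == "9"], "WOBBLE")

  # 488.1 has four G:C pairs around its A:A mismatch at 11:19
  p488 <- pairing_profile(v[["488.1"]])
  expect_equal(p488$gc_count, 4L)
  expect_identical(p488$pairs$class[p488$pairs$loop_pos == "11"], "MISMATCH")

  # a deleted pairing partner yields UNPAIRED
  res <- v[["980"]]$residues
  res[["18"]] <- "-"
  pdel <- pairing_profile(thf_variant("980.99", res, source = "artificial"))
  expect_identical(pdel$pairs$class[pdel$pairs$loop_pos == "12"], "UNPAIRED")
})

test_that("point-mutation distances reproduce the documented relationships", {
  v <- make_variant_fixtures()
  expect_equal(point_mutation_distance(v[["980"]], v[["980"]]), 0L)
  expect_equal(point_mutation_distance(v[["980"]], v[["3SUX"]]), 1L)
  expect_equal(point_mutation_distance(v[["980"]], v[["593"]]), 2L)
  expect_equal(point_mutation_distance(v[["980"]], v[["148"]]), 1L)
  expect_equal(point_mutation_distance(v[["980"]], v[["158"]]), 1L)
  expect_equal(point_mutation_distance(v[["980"]], v[["4LVV"]]), 8L)
  # insertion present in only one variant counts as one mutation
  expect_equal(point_mutation_distance(v[["593"]], v[["894"]]), 1L)
  # symmetry on the full fixture set
  for (a in v) for (b in v)
    expect_equal(point_mutation_distance(a, b), point_mutation_distance(b, a))
})

test_that("point-mutation distance is a metric on random signatures", {
  set.seed(42)
  alphabet <- c("A", "C", "G", "U", "-")
  rand_variant <- function(id)
    test_variant(id, paste(sample(alphabet, 8, replace = TRUE), collapse = ""))
  for (rep in 1:25) {
    x <- rand_variant("x"); y <- rand_variant("y"); z <- rand_variant("z")
    dxy <- point_mutation_distance(x, y)
    dyz <- point_mutation_distance(y, z)
    dxz <- point_mutation_distance(x, z)
    expect_equal(point_mutation_distance(x, x), 0L)
    expect_equal(dxy, point_mutation_distance(y, x))
    expect_lte(dxz, dxy + dyz)
  }
})

test_that("family components partition variants by mutation closeness", {
  v <- make_variant_fixtures()
  expect_equal(family_components(v["980"]), list("980"))

  trio <- list(v[["980"]], v[["3SUX"]], v[["4LVV"]])
  fams <- family_components(trio)
  expect_equal(fams, list(c("3SUX", "980"), "4LVV"))

  # transitive chain: a-b and b-c at distance 2, a-c at distance 4
  a <- test_variant("a", "AAAAAAAA")
  b <- test_variant("b", "AAAAAAGG")
  cc <- test_variant("c", "AAAAGGGG")
  expect_equal(point_mutation_distance(a, cc), 4L)
  expect_equal(family_components(list(a, b, cc)), list(c("a", "b", "c")))

  # partition property and input-order invariance on the fixture set
  fams <- family_components(v)
  ids <- vapply(v, function(x) x$id, "")
  expect_setequal(unlist(fams), ids)
  expect_equal(sum(lengths(fams)), length(ids))
  expect_equal(family_components(rev(v)), fams)
})

test_that("consensus applies the inclusive 75% threshold and R/Y/W codes", {
  col <- function(x) matrix(x, ncol = 1)
  expect_equal(as.character(consensus(col(c("G", "G", "G")))), "G")
  expect_equal(as.character(consensus(col(c("A", "A", "A", "G")))), "A")
  expect_equal(as.character(consensus(col(c("A", "A", "G", "G")))), "R")
  expect_equal(as.character(consensus(col(c("C", "C", "U", "U")))), "Y")
  expect_equal(as.character(consensus(col(c("A", "A", "U", "U")))), "W")
  expect_equal(as.character(consensus(col(c("A", "C", "G", "G")))), "N")
  expect_equal(as.character(consensus(col(c("-", "-", "A")))), "-")
})

test_that("consensus is idempotent", {
  v <- make_variant_fixtures()
  cons <- consensus(v)
  expect_equal(as.character(consensus(as.character(cons))),
               as.character(cons))
})

test_that("signature FASTA round-trips variants including insertions", {
  v <- make_variant_fixtures()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_signature_fasta(v, path)
  back <- read_signature_fasta(path)
  expect_equal(length(back), length(v))
  for (id in names(v)) {
    orig <- v[[id]]
    got <- back[[which(vapply(back, function(x) x$id, "") == id)]]
    expect_equal(got$residues, orig$residues)
    expect_equal(got$stem_length_bp, orig$stem_length_bp)
    expect_equal(got$source, orig$source)
  }
  # the insertion label survives the round trip
  v894 <- back[[which(vapply(back, function(x) x$id, "") == "894")]]
  expect_true("6.1" %in% names(v894$residues))
  expect_equal(unname(v894$residues[["6.1"]]), "G")
})

test_that("signature report carries families, pairs and reference distance", {
  v <- make_variant_fixtures()
  rep <- signature_report(v, reference = "4LVV")
  expect_equal(nrow(rep), length(v))
  expect_equal(rep$dist_to_reference[rep$id == "4LVV"], 0L)
  expect_equal(rep$dist_to_reference[rep$id == "980"], 8L)
  expect_equal(rep$gc_count[rep$id == "488.1"], 4L)
  expect_true(all(rep$family >= 1L))
})

test_that("position labels order insertions between their neighbours", {
  expect_equal(sort_position_labels(c("7", "6.1", "6", "23", "1")),
               c("1", "6", "6.1", "7", "23"))
  expect_error(sort_position_labels("x"), "malformed")
})
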