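toy <- transcript_model("TOY", "ATGTGCGGATAA")

test_that("transcript models are validated", {
  expect_equal(toy$protein_length, 3L)
  expect_error(transcript_model("X", "ATGTGCGGATA"), "divisible")
  expect_error(transcript_model("X", "TTGTGCGGATAA"), "ATG")
  expect_error(transcript_model("X", "ATGTGCGGAGGG"), "stop")
  expect_error(transcript_model("X", "ATGTAAGGATAA"), "internal stop")
  expect_error(
    transcript_model("X", "ATGTGCGGATAA",
                     data.frame(name = "d", start_aa = 1, end_aa = 5)),
    "outside")
})

test_that("canonical effect classes are called on the 4-codon toy CDS", {
  # codon 2 TGC -> TGA: stop gained
  call <- call_consequence(toy, 6, "C", "A")
  expect_equal(call$effect, "nonsense")
  expect_equal(call$truncation_aa, 2L)
  # initiator ATG -> GTG
  call <- call_consequence(toy, 1, "A", "G")
  expect_equal(call$effect, "start_loss")
  expect_equal(call$codon_index, 1L)
  # single-base deletion in codon 2 shifts the frame
  call <- call_consequence(toy, 4, "TG", "T")
  expect_equal(call$effect, "frameshift")
  # 3-base in-frame deletion removing codon 3 entirely (anchored at pos 6)
  call <- call_consequence(toy, 6, "CGGA", "C")
  expect_equal(call$effect, "inframe_indel")
  expect_true(is.na(call$truncation_aa))
  # synonymous wobble change GGA -> GGG
  expect_equal(call_consequence(toy, 9, "A", "G")$effect, "synonymous")
  # missense TGC -> AGC with residues reported
  call <- call_consequence(toy, 4, "T", "A")
  expect_equal(call$effect, "missense")
  expect_equal(call$aa_ref, "C")
  expect_equal(call$aa_alt, "S")
  expect_equal(call$codon_index, 2L)
})

test_that("frameshift truncation lands on the first shifted-frame stop", {
  # ATG AAA TAC GAT TAA: deleting pos 4 (A) shifts codon 2 to AAT ACG ATT AA
  # -> no stop before CDS end, truncation absent
  tx <- transcript_model("FS", "ATGAAATACGATTAA")
  call <- call_consequence(tx, 4, "AA", "A")
  expect_equal(call$effect, "frameshift")
  expect_true(is.na(call$truncation_aa))
  # deleting one T of ATG AAC TTA ... brings TAG into frame at codon 3
  tx2 <- transcript_model("FS2", "ATGAACTTAGTATGA")
  call <- call_consequence(tx2, 7, "TT", "T")
  expect_equal(call$effect, "frameshift")
  expect_equal(call$truncation_aa, 3L)
  expect_equal(call$truncation_aa,
               oracle_consequence(tx2, 7, "TT", "T")$truncation_aa)
})

test_that("ref mismatches error and out-of-CDS positions are noncoding", {
  expect_error(call_consequence(toy, 6, "G", "A"), "does not match")
  expect_equal(call_consequence(toy, 13, "A", "T")$effect, "noncoding")
  expect_equal(call_consequence(toy, 0, "A", "T")$effect, "noncoding")
  expect_error(call_consequence(toy, 12, "AA", "A"), "beyond")
})

test_that("consequence calls agree with the full-translation oracle", {
  set.seed(101)
  for (i in 1:300) {
    tx <- gen_transcript("R", n_codons = sample(4:40, 1), seed = i)
    v <- random_variant(tx)
    if (v$ref == v$alt) next
    got <- call_consequence(tx, v$pos, v$ref, v$alt)
    want <- oracle_consequence(tx, v$pos, v$ref, v$alt)
    expect_equal(got$effect, want$effect,
                 info = sprintf("cds=%s pos=%d %s>%s", tx$cds, v$pos,
                                v$ref, v$alt))
    if (want$effect %in% c("nonsense", "frameshift")) {
      expect_equal(got$truncation_aa, want$truncation_aa,
                   info = sprintf("cds=%s pos=%d %s>%s", tx$cds, v$pos,
                                  v$ref, v$alt))
    }
  }
})

test_that("domains partition into retained/lost/partial exactly once", {
  doms <- data.frame(name = c("A", "B"), start_aa = c(10, 600),
                     end_aa = c(100, 900))
  res <- domains_affected(1037, 560, doms)
  expect_equal(res$retained, "A")
  expect_equal(res$lost, "B")
  expect_equal(res$partial, character(0))
  # truncation at residue 1 removes everything
  res <- domains_affected(1037, 1, doms)
  expect_equal(sort(res$lost), c("A", "B"))
  # a domain straddling the cut is partial
  res <- domains_affected(1040, 1008,
                          data.frame(name = "LRR", start_aa = 1000,
                                     end_aa = 1020))
  expect_equal(res$partial, "LRR")
  # property: each domain in exactly one bucket
  set.seed(7)
  for (i in 1:50) {
    L <- sample(50:2000, 1)
    t_aa <- sample(L, 1)
    k <- sample(1:5, 1)
    s <- sort(sample(L, k))
    e <- pmin(s + sample(0:100, k, TRUE), L)
    dd <- data.frame(name = paste0("d", 1:k), start_aa = s, end_aa = e)
    res <- domains_affected(L, t_aa, dd)
    expect_setequal(c(res$retained, res$lost, res$partial), dd$name)
    expect_equal(length(res$retained) + length(res$lost) +
                   length(res$partial), k)
  }
  expect_error(domains_affected(100, 50,
                                data.frame(name = "x", start_aa = 90,
                                           end_aa = 120)),
               "outside")
})

test_that("truncated fraction matches the removed-residue count", {
  expect_equal(truncated_fraction(248, 211), 38 / 248)
  expect_equal(truncated_fraction(1040, 1008), 33 / 1040)
  expect_equal(truncated_fraction(10, 1), 1)
  expect_error(truncated_fraction(100, 101), "protein_length")
  expect_error(truncated_fraction(100, 0), "protein_length")
})

test_that("damaging-variant selection applies the consensus AND rule", {
  calls <- data.frame(
    variant_id = c("v_non", "v_syn", "v_mis1", "v_mis2", "v_fs", "v_sl"),
    effect = c("nonsense", "synonymous", "missense", "missense",
               "frameshift", "start_loss"))
  labels <- data.frame(
    variant_id = c("v_mis1", "v_mis2"),
    polyphen_label = c("probably damaging", "probably damaging"),
    sift_label = c("damaging", "tolerated"))
  expect_equal(select_damaging(calls, mode = "truncating_only"),
               c("v_non", "v_fs", "v_sl"))
  expect_equal(
    select_damaging(calls, labels, "truncating_plus_consensus_missense"),
    c("v_non", "v_mis1", "v_fs", "v_sl"))
  # both predictions must be at their most deleterious category
  labels2 <- labels
  labels2$polyphen_label[1] <- "possibly damaging"
  expect_false("v_mis1" %in%
    select_damaging(calls, labels2, "truncating_plus_consensus_missense"))
  # missing labels in consensus mode error with the variant ids
  expect_error(select_damaging(calls, labels[1, ],
                               "truncating_plus_consensus_missense"),
               "v_mis2")
  expect_error(select_damaging(calls, NULL,
                               "truncating_plus_consensus_missense"),
               "labels required")
})

test_that("enlarging the selection mode never drops a variant", {
  set.seed(31)
  effects <- c("nonsense", "frameshift", "start_loss", "missense",
               "synonymous", "inframe_indel")
  for (i in 1:20) {
    n <- sample(3:12, 1)
    calls <- data.frame(variant_id = paste0("v", 1:n),
                        effect = sample(effects, n, TRUE))
    labels <- data.frame(
      variant_id = calls$variant_id,
      polyphen_label = sample(c("probably_damaging", "benign"), n, TRUE),
      sift_label = sample(c("damaging", "tolerated"), n, TRUE))
    narrow <- select_damaging(calls, labels, "truncating_only")
    wide <- select_damaging(calls, labels,
                            "truncating_plus_consensus_missense")
    expect_true(all(narrow %in% wide))
  }
})
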