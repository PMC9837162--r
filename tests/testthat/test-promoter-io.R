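test_that("FASTA + metadata round-trips through write and read", {
  set.seed(11)
  co <- makeCohort(
    replicate(3, randomSeq()),
    families = c("globulin", "albumin", "beta_amylase"),
    groups = c("food", "food", "non_food"),
    species = c("Zea mays", "Oryza sativa", "Pinus sylvestris"))
  dir <- tempfile("rt"); dir.create(dir)
  fa <- file.path(dir, "c.fa"); tsv <- file.path(dir, "c.tsv")
  writePromoterCohort(co, fa, tsv)
  back <- readPromoterCohort(fa, tsv)
  expect_identical(recordIds(back), recordIds(co))
  expect_identical(as.character(promoterSequences(back)),
                   as.character(promoterSequences(co)))
  expect_identical(as.data.frame(cohortInfo(back)),
                   as.data.frame(cohortInfo(co)))

  # writing twice produces byte-identical files
  fa2 <- file.path(dir, "c2.fa"); tsv2 <- file.path(dir, "c2.tsv")
  writePromoterCohort(co, fa2, tsv2)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fa2, "raw", file.size(fa2)))
  expect_identical(readBin(tsv, "raw", file.size(tsv)),
                   readBin(tsv2, "raw", file.size(tsv2)))

  # empty cohort round-trips too
  empty <- co[integer(0)]
  writePromoterCohort(empty, fa2, tsv2)
  expect_length(readPromoterCohort(fa2, tsv2), 0L)
})

test_that("sequences are normalized: uppercase, U mapped to T", {
  lower <- tolower(randomSeq())
  rna <- chartr("T", "U", randomSeq())
  co <- makeCohort(c(lower, rna), ids = c("lc", "rna"))
  stored <- as.character(promoterSequences(co))
  expect_identical(stored[["lc"]], toupper(lower))
  expect_identical(stored[["rna"]], chartr("U", "T", rna))
  expect_false(grepl("U", stored[["rna"]]))
})

test_that("validation rejects bad lengths, tokens, duplicates and mismatches", {
  good <- randomSeq()
  meta <- data.frame(record_id = c("a", "b"), species = "sp",
                     gene_family = "globulin", group = "food")

  # wrong length names the offending record
  p <- writeRawPair(c("a", "b"), c(good, substr(good, 1, 89)), meta)
  expect_error(readPromoterCohort(p$fasta, p$metadata), "b")

  # unknown gene_family / group tokens
  bad_meta <- meta; bad_meta$gene_family <- c("globulin", "gliadin")
  p <- writeRawPair(c("a", "b"), c(good, randomSeq()), bad_meta)
  expect_error(readPromoterCohort(p$fasta, p$metadata), "gliadin")
  bad_meta <- meta; bad_meta$group <- c("food", "feral")
  p <- writeRawPair(c("a", "b"), c(good, randomSeq()), bad_meta)
  expect_error(readPromoterCohort(p$fasta, p$metadata), "feral")

  # duplicated ids
  p <- writeRawPair(c("a", "a"), c(good, randomSeq()),
                    data.frame(record_id = c("a", "a"), species = "sp",
                               gene_family = "globulin", group = "food"))
  expect_error(readPromoterCohort(p$fasta, p$metadata), "[Dd]uplicat")

  # record present in only one source
  p <- writeRawPair(c("a", "b"), c(good, randomSeq()),
                    meta[meta$record_id == "a", , drop = FALSE])
  expect_error(readPromoterCohort(p$fasta, p$metadata), "one-to-one")

  # non-IUPAC character is a hard error, not a filter case
  expect_error(makeCohort(chartr("A", "X", good)), "IUPAC")
})

test_that("filterAmbiguous routes IUPAC-ambiguous records and is idempotent", {
  set.seed(12)
  seqs <- replicate(5, randomSeq())
  substr(seqs[2], 45, 45) <- "R"
  substr(seqs[4], 1, 1) <- "W"
  co <- makeCohort(seqs)
  out <- filterAmbiguous(co)
  expect_length(out$kept, 3L)
  expect_identical(out$removed, c("rec_02", "rec_04"))
  # partition: kept ids + removed ids == input ids, order preserved
  expect_identical(sort(c(recordIds(out$kept), out$removed)),
                   sort(recordIds(co)))
  expect_identical(recordIds(out$kept), c("rec_01", "rec_03", "rec_05"))

  # a single N anywhere routes the record to removed
  n_seq <- randomSeq(); substr(n_seq, 90, 90) <- "N"
  out_n <- filterAmbiguous(makeCohort(n_seq, ids = "with_n"))
  expect_identical(out_n$removed, "with_n")

  # all-ACGT cohort is untouched; applying twice equals applying once
  clean <- filterAmbiguous(out$kept)
  expect_identical(clean$removed, character(0))
  expect_identical(as.character(promoterSequences(clean$kept)),
                   as.character(promoterSequences(out$kept)))
})

test_that("partitionCohort splits losslessly with sorted labels", {
  set.seed(13)
  co <- makeCohort(replicate(5, randomSeq()),
                   groups = c("food", "non_food", "food", "food", "non_food"),
                   families = c("albumin", "albumin", "globulin", "albumin",
                                "globulin"))
  by_grp <- partitionCohort(co, by = "group")
  expect_identical(names(by_grp), c("food", "non_food"))
  expect_identical(vapply(by_grp, length, integer(1)),
                   c(food = 3L, non_food = 2L))

  # concatenating sub-cohorts in label order permutes the input, no loss
  all_ids <- unlist(lapply(by_grp, recordIds), use.names = FALSE)
  expect_setequal(all_ids, recordIds(co))
  expect_length(all_ids, length(co))

  single <- partitionCohort(makeCohort(randomSeq()), by = "gene_family")
  expect_identical(names(single), "globulin")
  expect_identical(partitionCohort(co[integer(0)], by = "group"),
                   setNames(list(), character(0)))
})
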