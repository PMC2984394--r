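strict_seq <- paste0(strrep("A", 20), "LGGGGADVN", "GGGG")   # 33-mer

test_that("motif classification follows the positional rules", {
  r <- classify_repeat(strict_seq)
  expect_equal(r$class, "L8N")
  expect_true(r$strict)
  # position 21 not leucine with the sole loop Asn at 29: Asn without motif
  s2 <- strict_seq; substr(s2, 21, 21) <- "A"
  r2 <- classify_repeat(s2)
  expect_equal(r2$class, "Asn_non_L8N")
  expect_false(r2$strict)
  # no asparagine anywhere in the loop region
  s3 <- strict_seq; substr(s3, 29, 29) <- "D"
  expect_equal(classify_repeat(s3)$class, "non_Asn")
  # L8N without the stringent consensus (position 26 outside {A, C})
  s4 <- strict_seq; substr(s4, 26, 26) <- "G"
  r4 <- classify_repeat(s4)
  expect_equal(r4$class, "L8N")
  expect_false(r4$strict)
  # any loop asparagine with leucine eight upstream qualifies, not only 29
  s5 <- paste0(strrep("A", 16), "L", strrep("A", 7), "N", strrep("A", 8))
  expect_equal(classify_repeat(s5)$class, "L8N")
  # case-insensitive
  expect_equal(classify_repeat(tolower(strict_seq))$class, "L8N")
  expect_error(classify_repeat(strrep("A", 20)), "unclassifiable")
})

test_that("class counts partition the collection and strict nests in L8N", {
  db <- generate_ar_database(small_ar_spec(80), seed = 3)
  db <- classify_ars(db[setdiff(names(db), c("class", "strict"))])
  tab <- tabulate_ar_classes(db)
  g <- function(x) tab$repeats[tab$group == x]
  expect_equal(g("L8N") + g("Asn_non_L8N") + g("non_Asn"), g("total"))
  expect_equal(g("Asn_repeats"), g("L8N") + g("Asn_non_L8N"))
  expect_lte(g("L8N_strict"), g("L8N"))
  expect_true(all(db$strict[db$class != "L8N"] == FALSE))
  expect_equal(sum(tab$percent[tab$group %in%
                                 c("L8N", "Asn_non_L8N", "non_Asn")]), 100)
})

test_that("tabulation of tiny hand-built collections is exact", {
  db <- data.frame(
    protein = c("p1", "p1", "p2"), identifier = c("P1", "P1", "P2"),
    position = c(1, 2, 1),
    sequence = c(strict_seq,
                 sub("L", "A", strict_seq),      # Asn_non_L8N
                 gsub("N", "D", strict_seq)))    # non_Asn
  tab <- tabulate_ar_classes(classify_ars(validate_fixture(db)))
  g <- function(x) tab$repeats[tab$group == x]
  expect_equal(c(g("L8N"), g("Asn_non_L8N"), g("non_Asn")), c(1, 1, 1))
  expect_equal(tab$proteins[tab$group == "total"], 2)
  empty <- tabulate_ar_classes(classify_ars(validate_fixture(db[0, ])))
  expect_true(all(empty$repeats == 0))
})

test_that("database reading handles TSV, CSV and FASTA with deduplication", {
  db <- generate_ar_database(small_ar_spec(40), seed = 11)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ar_database(db, tsv)
  back <- read_ar_database(tsv)
  expect_equal(back$sequence, db$sequence)
  expect_equal(back$identifier, db$identifier)
  expect_equal(as.character(back$class), as.character(db$class))  # extras kept

  # CSV dialect with synonym headers
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(Name = db$protein, Accession = db$identifier,
                              Pos = db$position, Seq = db$sequence),
                   csv, row.names = FALSE, quote = FALSE)
  back2 <- read_ar_database(csv)
  expect_equal(back2$sequence, db$sequence)

  # FASTA dialect with identifier|protein|position headers
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", db$identifier, "|", db$protein, "|", db$position,
                    "\n", db$sequence), fa)
  back3 <- read_ar_database(fa)
  expect_equal(sort(back3$sequence), sort(db$sequence))

  # duplicate (identifier, position) records collapse keeping the first
  dup <- rbind(db[1, ], db[1, ], db[2, ])
  dup$sequence[2] <- strict_seq
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ar_database(dup, f2)
  dd <- read_ar_database(f2)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$sequence[1], db$sequence[1])

  # empty file gives an empty collection
  f3 <- withr::local_tempfile(fileext = ".tsv")
  file.create(f3)
  expect_equal(nrow(read_ar_database(f3, format = "tsv")), 0)

  # malformed inputs carry location information
  f4 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">only_two|fields", "ACDEF"), f4)
  expect_error(read_ar_database(f4), "record 1")
  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein,identifier,position", "x,y,1"), f5)
  expect_error(read_ar_database(f5), "sequence")
})

test_that("length filtering reports the excluded fraction", {
  db <- validate_fixture(data.frame(
    protein = "p", identifier = "P", position = 1:5,
    sequence = c(strrep("A", 20), strrep("A", 32), strrep("A", 33),
                 strrep("A", 34), strrep("A", 36))))
  lf <- length_filter(db)
  expect_equal(nrow(lf$db), 3)
  expect_equal(lf$excluded_fraction, 0.4)
  all33 <- validate_fixture(data.frame(protein = "p", identifier = "P",
                                       position = 1:3,
                                       sequence = rep(strict_seq, 3)))
  expect_equal(length_filter(all33)$excluded_fraction, 0)
  expect_error(length_filter(db, min = 35, max = 32), "min")
})

test_that("consensus takes the per-position mode with alphabetical ties", {
  seq_a <- strict_seq
  seq_b <- paste0("C", substr(strict_seq, 2, 33))
  db <- validate_fixture(data.frame(
    protein = "p", identifier = "P", position = 1:10,
    sequence = c(rep(seq_a, 6), rep(seq_b, 4))))
  cons <- ar_consensus(db)
  expect_equal(as.character(cons), seq_a)       # 6/4 majority at position 1
  expect_length(attr(cons, "ties"), 0)
  db5 <- validate_fixture(data.frame(
    protein = "p", identifier = "P", position = 1:10,
    sequence = c(rep(seq_a, 5), rep(seq_b, 5))))
  cons5 <- ar_consensus(db5)
  expect_equal(substr(cons5, 1, 1), "A",        # tie A/C broken alphabetically
               ignore_attr = TRUE)
  expect_equal(attr(cons5, "ties"), 1L)
  expect_error(ar_consensus(validate_fixture(db[0, ])), "empty")
})

test_that("frequency matrix columns are distributions; consensus is argmax", {
  db1 <- validate_fixture(data.frame(protein = "p", identifier = "P",
                                     position = 1, sequence = strict_seq))
  pfm1 <- ar_frequency_matrix(db1)
  expect_true(all(apply(pfm1, 2, max) == 1))    # one-hot columns
  expect_equal(max(abs(colSums(pfm1) - 1)), 0)

  seq_b <- paste0("C", substr(strict_seq, 2, 33))
  db2 <- validate_fixture(data.frame(protein = "p", identifier = "P",
                                     position = 1:2,
                                     sequence = c(strict_seq, seq_b)))
  pfm2 <- ar_frequency_matrix(db2)
  expect_equal(unname(pfm2["A", 1]), 0.5)
  expect_equal(unname(pfm2["C", 1]), 0.5)

  db <- generate_ar_database(small_ar_spec(100), seed = 5)
  keep <- length_filter(db)$db
  pfm <- ar_frequency_matrix(keep)
  expect_equal(max(abs(colSums(pfm) - 1)), 0, tolerance = 1e-9)
  cons <- ar_consensus(keep)
  chars <- strsplit(as.character(cons), "")[[1]]
  aa <- pfm[setdiff(rownames(pfm), "X"), ]
  expect_equal(chars, rownames(aa)[apply(aa, 2, which.max)])
  # a 32-mer contributes X only at the padding position
  db32 <- validate_fixture(data.frame(protein = "p", identifier = "P",
                                      position = 1,
                                      sequence = strrep("A", 32)))
  pfm32 <- ar_frequency_matrix(db32)
  expect_equal(unname(pfm32["X", 33]), 1)
  expect_equal(sum(pfm32["X", 1:32]), 0)
})

test_that("stringent-motif positions are more conserved in L8N repeats", {
  db <- generate_ar_database(synthetic_ar_spec(), seed = 19)
  keep <- length_filter(db)$db
  cons_l8n <- ar_conservation(ar_frequency_matrix(
    keep[keep$class == "L8N", ]))
  cons_other <- ar_conservation(ar_frequency_matrix(
    keep[keep$class == "Asn_non_L8N", ]))
  expect_true(all(cons_l8n[26:28] > cons_other[26:28]))
})

test_that("consensus export round-trips through FASTA", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_consensus_fasta(strict_seq, fa, name = "test_consensus")
  back <- Biostrings::readAAStringSet(fa)
  expect_equal(as.character(back[[1]]), strict_seq)
  expect_equal(names(back), "test_consensus")
})
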