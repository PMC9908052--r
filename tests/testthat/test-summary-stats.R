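test_that("reading a well-formed TSV preserves rows and field values", {
  rec <- make_records(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSummaryStats(path, trait = "urate", unit = "SD urate")
  expect_s4_class(ss, "SummaryStats")
  expect_equal(nrow(snpRecords(ss)), 3)
  expect_equal(snpRecords(ss)$rsid, rec$rsid)
  expect_equal(snpRecords(ss)$beta, rec$beta)
  expect_equal(nrow(rejectedRecords(ss)), 0)
})

test_that("invalid rows are rejected individually with a reason", {
  rec <- make_records(4)
  rec$se[2] <- 0
  rec$effect_allele[3] <- "I"
  ss <- SummaryStats(rec)
  expect_equal(nrow(snpRecords(ss)), 2)
  rej <- rejectedRecords(ss)
  expect_setequal(rej$rsid, rec$rsid[2:3])
  expect_equal(rej$reason[rej$rsid == rec$rsid[2]], "se not > 0")
  expect_equal(rej$reason[rej$rsid == rec$rsid[3]], "non-ACGT allele")
})

test_that("alias headers read via a dialect give the same table as canonical headers", {
  rec <- make_records(5)
  canon <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, canon, sep = "\t", quote = FALSE, row.names = FALSE)
  alias <- rec
  names(alias)[names(alias) == "effect_allele"] <- "A1"
  names(alias)[names(alias) == "other_allele"] <- "A2"
  names(alias)[names(alias) == "eaf"] <- "freq"
  names(alias)[names(alias) == "rsid"] <- "MarkerName"
  apath <- withr::local_tempfile(fileext = ".tsv")
  write.table(alias, apath, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- readSummaryStats(canon)
  b <- readSummaryStats(apath, dialect = c(
    rsid = "MarkerName", effect_allele = "A1", other_allele = "A2",
    eaf = "freq"))
  expect_equal(snpRecords(a), snpRecords(b))

  # dialect supplied as a YAML config file behaves identically
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(rsid = "MarkerName", effect_allele = "A1",
                        other_allele = "A2", eaf = "freq"), ypath)
  expect_equal(snpRecords(readSummaryStats(apath, dialect = ypath)),
               snpRecords(a))
})

test_that("a missing mandatory column is a format error naming the column", {
  rec <- make_records(2)
  rec$se <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSummaryStats(path), "se")
})

test_that("harmonize aligns effect alleles, flipping and flagging as needed", {
  ex <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   effect_allele = c("A", "C", "A", "A", "C"),
                   other_allele = c("G", "T", "T", "G", "A"),
                   eaf = c(0.3, 0.4, 0.50, 0.2, 0.6),
                   beta = c(0.1, 0.2, 0.1, 0.3, 0.15), se = 0.02,
                   stringsAsFactors = FALSE)
  ou <- data.frame(rsid = ex$rsid,
                   effect_allele = c("G", "C", "A", "T", "C"),
                   other_allele = c("A", "T", "T", "C", "G"),
                   eaf = c(0.7, 0.4, 0.52, 0.2, 0.5),
                   beta = c(0.2, 0.5, 0.1, 0.25, 0.3), se = 0.05,
                   stringsAsFactors = FALSE)
  h <- harmonize(SummaryStats(ex, "x"), SummaryStats(ou, "y"),
                 palindrome_eaf_limit = 0.42)
  p <- instrumentPairs(h)
  d <- droppedSnps(h)

  # rs1: outcome alleles swapped -> sign flip
  expect_true(p$flipped[p$rsid == "rs1"])
  expect_equal(p$beta_y[p$rsid == "rs1"], -0.2)
  # rs2: identical alleles -> untouched
  expect_false(p$flipped[p$rsid == "rs2"])
  expect_equal(p$beta_y[p$rsid == "rs2"], 0.5)
  # rs3: A/T palindrome at eaf 0.5 -> dropped
  expect_equal(d$reason[d$rsid == "rs3"], "palindromic_dropped")
  # rs4: outcome on opposite strand (T/C vs A/G) -> complemented, no flip
  expect_false(p$flipped[p$rsid == "rs4"])
  expect_equal(p$beta_y[p$rsid == "rs4"], 0.25)
  # rs5: C/A vs C/G is irreconcilable
  expect_equal(d$reason[d$rsid == "rs5"], "allele_mismatch")
  # accounting invariant
  expect_equal(nrow(p) + nrow(d), length(intersect(ex$rsid, ou$rsid)))
})

test_that("harmonization is idempotent and sign-consistent", {
  set.seed(7)
  for (rep in 1:5) {
    ex <- SummaryStats(make_records(20, seed = rep), "x")
    ou_rec <- make_records(20, seed = rep)
    # randomly swap allele coding on half the outcome records
    swap <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    tmp <- ou_rec$effect_allele[swap]
    ou_rec$effect_allele[swap] <- ou_rec$other_allele[swap]
    ou_rec$other_allele[swap] <- tmp
    ou_rec$beta <- rnorm(20, 0, 0.2)
    ou <- SummaryStats(ou_rec, "y")

    h1 <- harmonize(ex, ou)
    tabs <- pairs_to_tables(h1, ex)
    h2 <- harmonize(tabs$exposure, tabs$outcome)
    expect_equal(instrumentPairs(h2)$beta_y, instrumentPairs(h1)$beta_y)
    expect_false(any(instrumentPairs(h2)$flipped))

    # flipping coding + negating beta + complementing eaf changes nothing
    flipped <- ou_rec
    flipped[c("effect_allele", "other_allele")] <-
      flipped[c("other_allele", "effect_allele")]
    flipped$beta <- -flipped$beta
    flipped$eaf <- 1 - flipped$eaf
    h3 <- harmonize(ex, SummaryStats(flipped, "y"))
    expect_equal(instrumentPairs(h3)$beta_y, instrumentPairs(h1)$beta_y)
    expect_equal(nrow(instrumentPairs(h1)) + nrow(droppedSnps(h1)), 20)
  }
})

test_that("proxy substitution follows the highest-r2 rule with threshold and ties", {
  rec <- make_records(6)
  table <- SummaryStats(rec, "x")
  proxies <- data.frame(
    target = c("missA", "missA", "missB", "missC", "missC"),
    proxy = c(rec$rsid[5], rec$rsid[6], rec$rsid[6], rec$rsid[5], rec$rsid[4]),
    r2 = c(0.85, 0.95, 0.79, 0.9, 0.9), stringsAsFactors = FALSE)

  res <- substituteProxies(table, c(rec$rsid[1], "missA", "missB", "missC"),
                           proxies, r2_min = 0.8)
  rep <- res$report
  expect_equal(rep$status[rep$target == rec$rsid[1]], "present")
  # argmax r2
  expect_equal(rep$proxy[rep$target == "missA"], rec$rsid[6])
  expect_equal(rep$r2[rep$target == "missA"], 0.95)
  # best proxy below threshold -> excluded with reason
  expect_equal(rep$status[rep$target == "missB"], "excluded")
  expect_match(rep$reason[rep$target == "missB"], "r2 >= 0.8")
  # tie at r2 = 0.9 broken lexicographically
  expect_equal(rep$proxy[rep$target == "missC"],
               sort(c(rec$rsid[5], rec$rsid[4]))[1])
  expect_error(substituteProxies(table, "x", proxies, r2_min = 1.5),
               "r2_min")
})

test_that("the published proxy workflow shape is reproduced: 114 wanted, 10 missing, 6 proxied, 4 excluded", {
  set.seed(11)
  rec <- make_records(120, seed = 3)
  rec$rsid <- sprintf("rs%04d", 1:120)
  wanted <- rec$rsid[1:114]
  # 10 of the wanted SNPs are not genotyped
  missing <- wanted[105:114]
  table <- SummaryStats(rec[!(rec$rsid %in% missing), ], "x")
  # 6 have a usable proxy among the extra genotyped SNPs, 4 only poor ones
  extra <- rec$rsid[115:120]
  proxies <- rbind(
    data.frame(target = missing[1:6], proxy = extra,
               r2 = runif(6, 0.8, 1.0)),
    data.frame(target = missing[7:10], proxy = sample(extra, 4),
               r2 = runif(4, 0.3, 0.79)))
  res <- substituteProxies(table, wanted, proxies, r2_min = 0.8)
  expect_equal(sum(res$report$status == "proxied"), 6)
  expect_equal(sum(res$report$status == "excluded"), 4)
  expect_equal(nrow(snpRecords(res$table)), 110)
})
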