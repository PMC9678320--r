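test_that("shared hit fraction uses the min denominator", {
  a <- paste0("s", 1:10)
  expect_equal(shared_hit_fraction(a, a), 1)
  expect_equal(shared_hit_fraction(a, paste0("s", c(1:7, 11:13))), 0.7)
  expect_equal(shared_hit_fraction(a, paste0("x", 1:3)), 0)
  expect_equal(shared_hit_fraction(character(0), a), 0)
  expect_equal(shared_hit_fraction(a, paste0("s", 1:5)), 1)  # nesting
  expect_equal(shared_hit_fraction(a, paste0("s", c(1:5, 11:20)),
                                   denominator = "union"), 0.25)
})

make_random_hit_table <- function(seed) {
  set.seed(seed)
  n_q <- sample(3:10, 1)
  qs <- paste0("q", seq_len(n_q))
  rows <- do.call(rbind, lapply(qs, function(q) {
    subj <- sample(paste0("s", 1:15), sample(3:10, 1))
    data.frame(query_id = q, subject_id = subj, evalue = 1e-30,
               bitscore = 100, subject_taxid = 2001L,
               stringsAsFactors = FALSE)
  }))
  as_hit_table(rows)
}

test_that("single-linkage chains merge groups transitively", {
  # q1~q2 (0.8), q2~q3 (0.75), q1~q3 (0.1) -> one group by chaining
  tab <- as_hit_table(data.frame(
    query_id = rep(c("q1", "q2", "q3"), c(10, 20, 15)),
    subject_id = c(paste0("a", 1:10),                    # q1
                   paste0("a", 1:8), paste0("b", 1:12),  # q2: 8/10 with q1
                   paste0("b", 1:12), paste0("c", 1:3)), # q3: 12/15 with q2
    evalue = 1e-30, bitscore = 100, subject_taxid = 2001L))
  g <- group_queries(c("q1", "q2", "q3"), tab, threshold = 0.7)
  expect_length(g, 1)
  expect_equal(g[[1]]$query_ids, c("q1", "q2", "q3"))
  # below-threshold overlaps stay apart
  g2 <- group_queries(c("q1", "q3"), tab, threshold = 0.7)
  expect_length(g2, 2)
})

test_that("grouping matches a brute-force union-find oracle", {
  for (seed in 1:100) {
    tab <- make_random_hit_table(seed)
    cands <- unique(tab$query_id)
    hit_sets <- lapply(cands, function(q) tab$subject_id[tab$query_id == q])
    names(hit_sets) <- cands
    got <- group_queries(cands, tab, threshold = 0.7)
    got_parts <- lapply(got, `[[`, "query_ids")
    want <- brute_group_oracle(cands, hit_sets, 0.7)
    key <- function(parts) sort(vapply(parts, paste, "", collapse = ","))
    expect_equal(key(got_parts), key(want), info = paste("seed", seed))
    # partition covers candidates exactly once
    expect_setequal(unlist(got_parts), cands)
    expect_equal(anyDuplicated(unlist(got_parts)), 0)
    # input-order invariance
    got_rev <- group_queries(rev(cands), tab, threshold = 0.7)
    expect_equal(key(lapply(got_rev, `[[`, "query_ids")), key(got_parts))
    # raising the threshold only refines the partition
    finer <- lapply(group_queries(cands, tab, threshold = 0.9),
                    `[[`, "query_ids")
    for (f in finer) {
      expect_true(any(vapply(got_parts,
                             function(gp) all(f %in% gp), TRUE)))
    }
  }
})

test_that("hitless candidates become flagged singletons", {
  tab <- make_random_hit_table(1)
  expect_warning(g <- group_queries(c(unique(tab$query_id), "ghost"), tab),
                 "zero hits")
  parts <- lapply(g, `[[`, "query_ids")
  expect_true(list("ghost") %in% parts)
})

test_that("user group files load verbatim and reject overlap", {
  f <- tempfile()
  writeLines(c("og1\tq1,q2\ts1,s2,s3", "og2\tq3\ts4"), f)
  g <- load_user_groups(f)
  expect_length(g, 2)
  expect_equal(g[[1]]$query_ids, c("q1", "q2"))
  expect_equal(g[[2]]$hit_subject_ids, "s4")
  writeLines(c("og1\tq1,q2\ts1", "og2\tq2\ts2"), f)
  expect_error(load_user_groups(f), "more than one group")
  writeLines("og1\tq1\t", f)
  g3 <- load_user_groups(f)
  expect_equal(g3[[1]]$flag, "no_hits")
})

test_that("group FASTA deduplicates shared hits and caps per query", {
  ht <- make_hit_table(planted_scenario(seed = 2, n_queries = 2,
                                        fraction_hgt = 1))
  tab <- ht$table
  grp <- group_queries(unique(tab$query_id), tab)[[1]]  # singleton
  f <- tempfile(fileext = ".fasta")
  build_group_fasta(grp, ht$query_seqs, ht$db_seqs, tab, f)
  ids <- names(read_fasta(f))
  expect_equal(length(ids), 1 + 16)           # query + all its hits
  expect_true(all(grepl("\\|", setdiff(ids, grp$query_ids))))

  # cap 2 keeps the top-2 hits by bitscore
  f2 <- tempfile(fileext = ".fasta")
  expect_warning(
    build_group_fasta(grp, ht$query_seqs, ht$db_seqs, tab, f2,
                      max_hits_per_query = 2),
    "too small")
  ids2 <- names(read_fasta(f2))
  expect_equal(length(ids2), 3)
  hits_q <- hits_for_query(tab, grp$query_ids[1])
  top2 <- hits_q$subject_id[order(-hits_q$bitscore)][1:2]
  expect_setequal(sub("\\|.*$", "", setdiff(ids2, grp$query_ids)), top2)

  # two queries sharing hits write shared sequences once
  tab2 <- as_hit_table(data.frame(
    query_id = rep(c("qa", "qb"), each = 4),
    subject_id = c("h1", "h2", "h3", "h4", "h1", "h2", "h3", "h5"),
    evalue = 1e-30, bitscore = 100, subject_taxid = 2001L))
  seqs <- stats::setNames(rep("MKVLAE", 7),
                          c("qa", "qb", "h1", "h2", "h3", "h4", "h5"))
  grp2 <- group_queries(c("qa", "qb"), tab2)[[1]]
  expect_equal(grp2$query_ids, c("qa", "qb"))
  f3 <- tempfile(fileext = ".fasta")
  build_group_fasta(grp2, seqs, seqs, tab2, f3)
  expect_equal(length(names(read_fasta(f3))), 7)  # no duplicated shared hits
})

test_that("alignment invocation follows the configured command template", {
  mock <- local_mock_tool("fakealigner",
    'echo "$@" > "$FAKE_LOG"; cat "$1"')
  log <- tempfile()
  withr::local_envvar(FAKE_LOG = log)
  f <- tempfile(fileext = ".fasta")
  write_fasta(c(a = "MKV", b = "MKL", c = "MQV"), f)
  out <- align_group(f, mafft_cmd = "fakealigner {input}")
  expect_equal(readLines(log), f)
  expect_setequal(names(read_fasta(out)), c("a", "b", "c"))
})

test_that("missing or failing external tools raise actionable errors", {
  f <- tempfile(fileext = ".fasta")
  write_fasta(c(a = "MKV", b = "MKL"), f)
  expect_error(align_group(f, mafft_cmd = "no-such-aligner-xyz {input}"),
               "mafft")
  expect_error(
    align_group(f, trim = TRUE,
                mafft_cmd = "cat {input}",
                trimal_cmd = "no-such-trimmer-xyz -in {input} -out {output}"),
    "trimal")
  failing <- local_mock_tool("failingtool", 'echo "boom" >&2; exit 3')
  expect_error(align_group(f, mafft_cmd = "failingtool {input}"), "boom")
})

test_that("mafft aligns identical sequences without introducing gaps", {
  skip_if(Sys.which("mafft") == "", "mafft not on PATH")
  f <- tempfile(fileext = ".fasta")
  write_fasta(c(s1 = "MKVLAEQGHT", s2 = "MKVLAEQGHT", s3 = "MKVLAEQGHT"), f)
  aln <- read_fasta(align_group(f))
  expect_setequal(names(aln), c("s1", "s2", "s3"))
  expect_true(all(toupper(aln) == "MKVLAEQGHT"))
})
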