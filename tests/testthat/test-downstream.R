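# taxonomy with a nested donor hierarchy for origin classification:
# root -> Bacteria -> Proteobacteria -> species, plus fungal-style labels
origin_tax <- local({
  nodes <- data.frame(
    taxid = c(1L, 2L, 1224L, 4751L, 3001L, 3002L, 3003L, 4001L),
    parent = c(1L, 1L, 2L, 1L, 1224L, 1224L, 2L, 4751L),
    rank = c("no rank", "superkingdom", "phylum", "kingdom",
             "species", "species", "species", "species"))
  names_df <- data.frame(
    taxid = c(1L, 2L, 1224L, 4751L, 3001L, 3002L, 3003L, 4001L),
    name = c("root", "Bacteria", "Proteobacteria", "Fungi",
             "Proteo_sp1", "Proteo_sp2", "OtherBac_sp", "Fungus_sp"))
  taxonomy_from_dump(nodes, names_df)
})

test_that("origin assignment picks the deepest rank passing the threshold", {
  ranks <- c("Bacteria", "Proteobacteria")
  expect_equal(assign_origin(rep(3001L, 10), origin_tax, ranks), "Proteobacteria")
  # 8/10 proteobacteria, 2 other bacteria: fine rank passes at 0.8
  expect_equal(assign_origin(c(rep(3001L, 8), rep(3003L, 2)), origin_tax,
                             ranks), "Proteobacteria")
  # 6/10: falls back to the coarser rank
  expect_equal(assign_origin(c(rep(3001L, 6), rep(3003L, 4)), origin_tax,
                             ranks), "Bacteria")
  # an even bacteria/fungi split satisfies nothing
  expect_equal(assign_origin(c(rep(3001L, 5), rep(4001L, 5)), origin_tax,
                             ranks), "ambiguous")
  expect_equal(assign_origin(integer(0), origin_tax, ranks), "ambiguous")
})

test_that("a passing fine rank implies its coarser ancestor passes", {
  set.seed(21)
  ranks <- c("Bacteria", "Proteobacteria")
  for (i in 1:25) {
    taxids <- sample(c(3001L, 3002L, 3003L, 4001L), sample(3:12, 1),
                     replace = TRUE)
    fine_frac <- mean(vapply(taxids, function(t)
      "Proteobacteria" %in% lineage_names(origin_tax, t), TRUE))
    coarse_frac <- mean(vapply(taxids, function(t)
      "Bacteria" %in% lineage_names(origin_tax, t), TRUE))
    if (fine_frac >= 0.8) expect_gte(coarse_frac, 0.8)
    got <- assign_origin(taxids, origin_tax, ranks)
    want <- if (fine_frac >= 0.8) "Proteobacteria"
      else if (coarse_frac >= 0.8) "Bacteria" else "ambiguous"
    expect_equal(got, want)
  }
})

test_that("constraint trees force query + Ingroup monophyly and keep all leaves", {
  aff <- c(q = "QUERY", i1 = "INGROUP", i2 = "INGROUP",
           d1 = "DONOR", d2 = "DONOR")
  nw <- build_constraint_tree(names(aff), "q", aff)
  expect_equal(nw, "((q,i1,i2),d1,d2);")
  t <- ape::read.tree(text = nw)
  expect_setequal(t$tip.label, names(aff))
  # zero ingroup leaves: nothing to constrain
  aff2 <- c(q = "QUERY", d1 = "DONOR", d2 = "DONOR")
  expect_warning(res <- build_constraint_tree(names(aff2), "q", aff2),
                 "nothing to constrain")
  expect_null(res)
})

test_that("random constraint trees re-parse to exactly the {query}+Ingroup clade", {
  set.seed(77)
  for (i in 1:100) {
    n_i <- sample(1:8, 1); n_d <- sample(1:8, 1); n_u <- sample(0:2, 1)
    leaves <- c("qq", paste0("ing", seq_len(n_i)), paste0("don", seq_len(n_d)),
                if (n_u) paste0("unk", seq_len(n_u)))
    aff <- stats::setNames(
      c("QUERY", rep("INGROUP", n_i), rep("DONOR", n_d),
        rep("UNKNOWN", n_u)), leaves)
    leaves <- sample(leaves)
    nw <- build_constraint_tree(leaves, "qq", aff)
    t <- ape::read.tree(text = nw)
    expect_setequal(t$tip.label, leaves)
    expect_equal(anyDuplicated(t$tip.label), 0)
    clade_node <- t$edge[t$edge[, 1] == length(t$tip.label) + 1 &
                         t$edge[, 2] > length(t$tip.label), 2]
    clade <- ape::extract.clade(t, clade_node)$tip.label
    expect_setequal(clade, c("qq", names(aff)[aff == "INGROUP"]))
  }
})

report_fixture <- c(
  "USER TREES",
  "",
  "Tree      logL    deltaL  bp-RELL    p-KH     p-SH    p-WKH    p-WSH       c-ELW       p-AU",
  "-------------------------------------------------------------------------------------------",
  "  1 -6731.65029       0   0.989 +  0.976 +      1 +  0.976 +  0.968 +    0.989 +  0.979 + ",
  "  2 -6740.72163  9.0713   0.0109 -  0.0236 -  0.276 -  0.0236 -  0.0317 -   0.0111 -  0.0194 - ")

test_that("topology-test reports parse to their printed values", {
  f <- tempfile(); writeLines(report_fixture, f)
  res <- parse_topology_report(f)
  expect_equal(res$topology, c("original", "constrained"))
  expect_equal(res$logL, c(-6731.65029, -6740.72163))
  expect_equal(res$p_AU, c(0.979, 0.0194))
  expect_equal(res$deltaL, c(0, 9.0713))
  # a report without the AU column is an error naming the field
  broken <- sub("p-AU", "p-XX", report_fixture)
  f2 <- tempfile(); writeLines(broken, f2)
  expect_error(parse_topology_report(f2), "p-AU")
  f3 <- tempfile(); writeLines("no table here", f3)
  expect_error(parse_topology_report(f3), "table")
})

test_that("the evaluation decision applies the AU rule at alpha", {
  f <- tempfile(); writeLines(report_fixture, f)
  res <- parse_topology_report(f)
  expect_equal(evaluate_decision(res, alpha = 0.05), "STRONG")  # p = 0.0194
  expect_equal(evaluate_decision(res, alpha = 0.01), "EQUAL")
  res$p_AU[2] <- 0.30
  expect_equal(evaluate_decision(res), "EQUAL")
  res$p_AU[2] <- 0.001
  expect_equal(evaluate_decision(res), "STRONG")
  # identical topologies cannot be distinguished
  res$p_AU[2] <- 0.999
  expect_equal(evaluate_decision(res), "EQUAL")
})

test_that("the evaluation toolchain is invoked per its command templates", {
  dir <- withr::local_tempdir()
  aln <- file.path(dir, "g.aln"); writeLines(c(">a", "MKV"), aln)
  orig <- file.path(dir, "orig.nwk"); writeLines("((a,b),c,d);", orig)
  cons <- file.path(dir, "cons.nwk"); writeLines("((a,b,c),d);", cons)
  fixture <- file.path(dir, "fixture.report")
  writeLines(report_fixture, fixture)
  log <- tempfile()
  withr::local_envvar(FIXTURE = fixture, TOOL_LOG = log)
  local_mock_tool("faketopo", paste0(
    'echo "$@" >> "$TOOL_LOG"\n',
    'for last; do :; done\n',
    'case "$last" in *.treefile) echo "((a,b,c),d);" > "$last";;',
    ' *) cp "$FIXTURE" "$last";; esac'))
  res <- run_topology_tests(
    aln, orig, cons,
    constrained_cmd = "faketopo -s {alignment} -g {constraint} {output}",
    test_cmd = "faketopo -s {alignment} -z {trees} {report}",
    workdir = file.path(dir, "wk"))
  calls <- readLines(log)
  expect_length(calls, 2)
  expect_match(calls[1], paste0("-s ", aln, " -g ", cons))
  expect_match(calls[2], "-z .*both\\.trees")
  expect_equal(res$p_AU[res$topology == "constrained"], 0.0194)
})
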