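make_catalog <- function(rows) {
  d <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("DISEASE/TRAIT\tMAPPED_GENE\tREPORTED GENE(S)\tPUBMEDID", rows), d)
  d
}

make_mesh_map <- function(rows) {
  d <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("trait\tmesh_id\ttree_numbers\tterm", rows), d)
  d
}

test_that("catalog parsing splits multi-gene cells and drops intergenic", {
  path <- make_catalog(c("Trait one\tTP53, BRCA1\tNR\t111",
                         "Trait one\tLINC01, intergenic\tNR\t112",
                         "Trait two\tAPOE - TOMM40\tNR\t113"))
  rec <- parse_gwas_catalog(path)
  expect_identical(nrow(rec), 3L)                  # one record per row
  expect_identical(length(unique(rec$trait)), 2L)
  expect_setequal(rec$genes[[1]], c("TP53", "BRCA1"))
  expect_identical(rec$genes[[2]], "LINC01")
  expect_setequal(rec$genes[[3]], c("APOE", "TOMM40"))  # " - " separator
  # lowercase symbols are normalized
  path2 <- make_catalog("Trait x\tbrca2\tNR\t114")
  expect_identical(parse_gwas_catalog(path2)$genes[[1]], "BRCA2")
})

test_that("missing required catalog columns are a named format error", {
  d <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("DISEASE/TRAIT\tOTHER", "t\tx"), d)
  expect_error(parse_gwas_catalog(d), "MAPPED_GENE")
})

test_that("the REPORTED GENE(S) column can be unioned in", {
  path <- make_catalog("Trait one\tTP53\tMYC, KRAS\t111")
  expect_identical(parse_gwas_catalog(path)$genes[[1]], "TP53")
  expect_setequal(parse_gwas_catalog(path, include_reported = TRUE)$genes[[1]],
                  c("TP53", "MYC", "KRAS"))
})

test_that("MeSH tree numbers truncate to C-category level-3 terms", {
  expect_identical(mesh_level3("C14.907.489.631"), "C14.907.489")
  expect_identical(mesh_level3("C04.588.180"), "C04.588.180")
  expect_identical(mesh_level3("D03.383.129"), NA_character_)  # not category C
  expect_identical(mesh_level3("C04.588"), NA_character_)      # depth 2
  expect_identical(mesh_level3(c("C01.100.200.300", "B05.200.300")),
                   c("C01.100.200", NA))
  expect_error(mesh_level3("C4.58"), "malformed")
  expect_error(mesh_level3("C04.58a"), "malformed")
})

test_that("aggregation unions trait genes under each level-3 ancestor", {
  cat <- make_catalog(c("t1\tA, B\tNR\t1",
                        "t2\tB, C\tNR\t2",
                        "t3\tD\tNR\t3",
                        "unmapped trait\tE\tNR\t4"))
  map <- make_mesh_map(c("t1\tD000001\tC04.588.180.100\tTerm one",
                         "t2\tD000002\tC04.588.180.200\tTerm two",
                         "t3\tD000003\tC04.111.222;C17.333.444\tTerm three"))
  rec <- parse_gwas_catalog(cat)
  expect_message(net <- aggregate_disease_genes(rec, read_mesh_map(map)),
                 "no MeSH mapping")
  # two traits under one level-3 ancestor merge to the union
  expect_setequal(net$genes[["C04.588.180"]], c("A", "B", "C"))
  # multi-ancestor trait contributes to both level-3 terms
  expect_identical(net$genes[["C04.111.222"]], "D")
  expect_identical(net$genes[["C17.333.444"]], "D")
  expect_setequal(names(net$genes), c("C04.588.180", "C04.111.222", "C17.333.444"))
  # all ids match the level-3 pattern
  expect_true(all(grepl("^C\\d{2}(\\.\\d{3}){2}$", names(net$genes))))
  # labels are the alphabetically first contributing term
  expect_identical(unname(net$labels["C04.588.180"]), "Term one")
  # duplicated records change nothing (union idempotence)
  net2 <- suppressMessages(aggregate_disease_genes(rbind(rec, rec),
                                                   read_mesh_map(map)))
  expect_identical(net2$genes, net$genes)
})

test_that("traits without a C-category level-3 ancestor are excluded", {
  cat <- make_catalog("t1\tA\tNR\t1")
  map <- make_mesh_map("t1\tD000001\tD03.383.129\tNot a disease")
  rec <- parse_gwas_catalog(cat)
  expect_error(suppressMessages(aggregate_disease_genes(rec, read_mesh_map(map))),
               NA)
  net <- suppressMessages(aggregate_disease_genes(rec, read_mesh_map(map)))
  expect_identical(length(net$genes), 0L)
})

small_net <- function(sets, labels = NULL) {
  ids <- names(sets)
  structure(list(genes = sets,
                 provenance = lapply(sets, function(g) rep("catalog", length(g))),
                 labels = setNames(if (is.null(labels)) ids else labels, ids)),
            class = "disease_network")
}

test_that("PPI expansion ranks one-hop neighbours by max score then symbol", {
  net <- small_net(list(`C01.001.001` = "A"))
  edges <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "D"),
                      score = c(0.95, 0.91, 0.92))
  out <- expand_with_ppi(net, edges, max_added = 1)
  # D is two hops away; B outranks C on score
  expect_identical(out$genes[[1]], c("A", "B"))
  expect_identical(out$provenance[[1]], c("catalog", "ppi_expansion"))
  out2 <- expand_with_ppi(net, edges, max_added = 10)
  expect_identical(out2$genes[[1]], c("A", "B", "C"))
  # symbol ascending breaks score ties
  tied <- data.frame(gene_a = c("A", "A"), gene_b = c("Z", "Y"),
                     score = c(0.95, 0.95))
  out3 <- expand_with_ppi(net, tied, max_added = 1)
  expect_identical(out3$genes[[1]], c("A", "Y"))
})

test_that("the score threshold is strict and expansion without edges is identity", {
  net <- small_net(list(`C01.001.001` = c("A", "B")))
  at_cut <- data.frame(gene_a = "A", gene_b = "X", score = 0.9)
  expect_identical(expand_with_ppi(net, at_cut)$genes, net$genes)
  none <- data.frame(gene_a = character(0), gene_b = character(0),
                     score = numeric(0))
  expect_identical(expand_with_ppi(net, none)$genes, net$genes)
})

test_that("expansion is monotone, capped, idempotent, and shrinks with threshold", {
  set.seed(2)
  genes <- sprintf("G%03d", 1:60)
  net <- small_net(list(`C01.001.001` = genes[1:5], `C02.002.002` = genes[6:8]))
  edges <- data.frame(gene_a = sample(genes, 300, replace = TRUE),
                      gene_b = sample(genes, 300, replace = TRUE),
                      score = runif(300, 0.5, 1.0))
  edges <- edges[edges$gene_a != edges$gene_b, ]
  for (thr in c(0.6, 0.8, 0.95)) {
    out <- expand_with_ppi(net, edges, score_threshold = thr, max_added = 10)
    for (id in names(net$genes)) {
      expect_true(all(net$genes[[id]] %in% out$genes[[id]]))  # seeds kept
      expect_lte(length(out$genes[[id]]) - length(net$genes[[id]]), 10)
      expect_false(any(duplicated(out$genes[[id]])))
    }
    # re-expansion recomputes from catalog genes: idempotent
    expect_identical(expand_with_ppi(out, edges, score_threshold = thr,
                                     max_added = 10)$genes, out$genes)
  }
  lo <- expand_with_ppi(net, edges, score_threshold = 0.6, max_added = 100)
  hi <- expand_with_ppi(net, edges, score_threshold = 0.9, max_added = 100)
  for (id in names(net$genes)) {
    expect_true(all(hi$genes[[id]] %in% lo$genes[[id]]))
  }
})

test_that("network summary counts diseases, genes and interactions", {
  net <- small_net(list(`C01.001.001` = c("A", "B"), `C02.002.002` = "B"))
  s <- network_summary(net)
  expect_identical(s[c("n_diseases", "n_genes", "n_interactions")],
                   list(n_diseases = 2L, n_genes = 2L, n_interactions = 3L))
  expect_equal(s$avg_genes_per_disease, 2)  # 3/2 rounds half away from zero
  empty <- small_net(setNames(list(), character(0)))
  s0 <- network_summary(empty)
  expect_equal(unlist(s0), c(n_diseases = 0, n_genes = 0, n_interactions = 0,
                             avg_genes_per_disease = 0))
})

test_that("STRING links read in both separators and normalize scores", {
  d <- withr::local_tempfile()
  writeLines(c("protein1 protein2 combined_score", "a b 950", "b c 900"), d)
  e <- read_string_links(d)
  expect_identical(e$gene_a, c("A", "B"))
  expect_equal(e$score, c(0.95, 0.9))
  d2 <- withr::local_tempfile()
  writeLines(c("protein1\tprotein2\tcombined_score", "a\tb\t123"), d2)
  expect_equal(read_string_links(d2)$score, 0.123)
  d3 <- withr::local_tempfile()
  writeLines(c("protein1 protein2 combined_score", "a a 500"), d3)
  expect_error(read_string_links(d3), "self-loop")
})
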