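test_that("bioassay tables load with outcome mapping and strict errors", {
  f <- write_assay_csv(tempfile(fileext = ".csv"),
                       c("m1,CCO,Active", "m2,CCN,Active", "m3,CCC,Inactive"))
  ds <- read_bioassay(f)
  expect_s3_class(ds, "bioassay_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(sum(ds$label == 1), 2)

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("cid,outcome", "m1,Active"), f2)
  expect_error(read_bioassay(f2), class = "qsar_format_error")

  f3 <- write_assay_csv(tempfile(fileext = ".csv"),
                        c("m1,CCO,Active", "m2,CCN,0", "m3,CCC,1",
                          "m4,CCS,Inconclusive"))
  err <- tryCatch(read_bioassay(f3), error = identity)
  expect_s3_class(err, "qsar_parse_error")
  expect_match(conditionMessage(err), "Inconclusive")
  expect_match(conditionMessage(err), "row 4")

  # tsv variant with custom column names
  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tstructure\tcall", "a\tCC\tactive", "b\tCN\tinactive"), f4)
  ds4 <- read_bioassay(f4, format = "tsv",
                       columns = c(id = "id", smiles = "structure",
                                   outcome = "call"))
  expect_equal(ds4$label, c(1L, 0L))
})

test_that("deduplication keeps first occurrences and drops inconsistent ids", {
  mk <- function(ids, labs) bioassay_dataset(ids, rep("CC", length(ids)), labs)
  expect_equal(deduplicate_bioassay(mk(c("A", "A", "B"), c(1, 1, 0)))$compound_id,
               c("A", "B"))
  expect_equal(deduplicate_bioassay(mk(c("A", "A", "B"), c(1, 0, 0)))$compound_id,
               "B")
  d3 <- mk(c("A", "B", "C"), c(1, 0, 1))
  expect_equal(deduplicate_bioassay(d3)$compound_id, c("A", "B", "C"))
  # idempotence
  once <- deduplicate_bioassay(mk(c("A", "A", "B", "C", "C"), c(1, 0, 0, 1, 1)))
  expect_identical(deduplicate_bioassay(once)$compound_id, once$compound_id)
})

test_that("imbalance ratio reproduces the benchmark panel extremes", {
  mk <- function(n1, n0) bioassay_dataset(
    paste0("c", seq_len(n1 + n0)), rep("CC", n1 + n0),
    c(rep(1, n1), rep(0, n0)))
  expect_equal(round(imbalance_ratio(mk(2601, 10826)), 2), 4.16)
  expect_equal(round(imbalance_ratio(mk(1006, 934)), 2), 1.08)
  expect_equal(imbalance_ratio(mk(50, 50)), 1)
  expect_error(imbalance_ratio(mk(10, 0)), class = "qsar_single_class_error")
})

test_that("random splits honour sizes, folds, determinism and coverage", {
  ds <- bioassay_dataset(paste0("c", 1:100), rep("CC", 100),
                         rep(c(1, 0), 50))
  plan <- split_train_test(ds, seed = 4)
  expect_length(plan$train_indices, 75)
  expect_length(plan$test_indices, 25)
  expect_equal(unname(table(plan$fold_assignment)), rep(15L, 5),
               ignore_attr = TRUE)
  plan2 <- split_train_test(ds, seed = 4)
  expect_identical(plan, plan2)
  expect_false(identical(plan$train_indices,
                         split_train_test(ds, seed = 5)$train_indices))

  small <- bioassay_dataset(paste0("c", 1:4), rep("CC", 4), c(1, 0, 1, 0))
  expect_error(split_train_test(small, k = 5), class = "qsar_format_error")

  # exact cover of 1..n, folds differ by at most one, across seeds and sizes
  for (s in 1:5) {
    n <- sample(20:90, 1)
    dsn <- bioassay_dataset(paste0("c", 1:n), rep("CC", n),
                            rep_len(c(1, 0), n))
    p <- split_train_test(dsn, train_fraction = 0.7, k = 4, seed = s)
    expect_setequal(c(p$train_indices, p$test_indices), seq_len(n))
    expect_length(intersect(p$train_indices, p$test_indices), 0)
    expect_lte(diff(range(table(p$fold_assignment))), 1)
  }

  # stratified draw preserves the class proportions of an imbalanced assay
  dsi <- bioassay_dataset(paste0("c", 1:200), rep("CC", 200),
                          c(rep(1, 40), rep(0, 160)))
  ps <- split_train_test(dsi, seed = 2, stratify = TRUE)
  expect_equal(sum(dsi$label[ps$train_indices]), 30)  # 0.75 * 40
})

test_that("split plans round-trip through their JSON sidecar", {
  ds <- bioassay_dataset(paste0("c", 1:40), rep("CC", 40), rep_len(c(1, 0), 40))
  plan <- split_train_test(ds, seed = 11)
  f <- tempfile(fileext = ".json")
  write_split_plan(plan, f)
  back <- read_split_plan(f)
  expect_equal(back$train_indices, plan$train_indices)
  expect_equal(back$fold_assignment, plan$fold_assignment)
  expect_equal(back$k, plan$k)
})

test_that("scaffold split keeps scaffold groups intact", {
  # ten structurally distinct ring systems -> granularity 1 -> 8/1/1
  smis10 <- c("c1ccccc1CC", "c1ccncc1CC", "C1CCCCC1C", "c1ccsc1CC",
              "C1CCCC1", "C1CCOC1", "c1ccc2ccccc2c1", "C1CCNC1",
              "C1CCSC1", "C1COCCN1")
  ds10 <- bioassay_dataset(paste0("m", 1:10), smis10, rep_len(c(1, 0), 10))
  sp <- scaffold_split(ds10)
  expect_equal(lengths(sp[c("train", "valid", "test")]),
               c(train = 8L, valid = 1L, test = 1L))

  # one shared scaffold is indivisible: everything trains
  ds1 <- bioassay_dataset(paste0("m", 1:10),
                          paste0(rep("c1ccccc1", 10),
                                 c("C", "CC", "CCC", "CCCC", "N", "CN", "O",
                                   "CO", "CCN", "CCO")),
                          rep_len(c(1, 0), 10))
  sp1 <- scaffold_split(ds1)
  expect_length(sp1$train, 10)

  # groups of sizes 5, 3, 1, 1 fill greedily largest-first
  smis <- c(paste0("c1ccccc1", c("C", "CC", "CCC", "N", "O")),      # benzene x5
            paste0("c1ccncc1", c("C", "CC", "N")),                  # pyridine x3
            "C1CCCCC1C",                                            # cyclohexane
            "c1ccsc1C")                                             # thiophene
  dsm <- bioassay_dataset(paste0("m", 1:10), smis, rep_len(c(1, 0), 10))
  spm <- scaffold_split(dsm)
  expect_equal(sort(spm$train), 1:8)      # benzene + pyridine groups
  expect_length(spm$valid, 1)
  expect_length(spm$test, 1)

  # no scaffold key may straddle two subsets
  for (g in spm$groups) {
    hit <- c(any(g %in% spm$train), any(g %in% spm$valid),
             any(g %in% spm$test))
    expect_equal(sum(hit), 1)
  }

  # unparseable SMILES are excluded with a warning
  dsb <- bioassay_dataset(paste0("m", 1:4),
                          c("c1ccccc1C", "QQ?", "CCO", "C1CCCCC1"),
                          c(1, 0, 1, 0))
  expect_warning(spb <- scaffold_split(dsb), "unparseable")
  expect_equal(spb$n_excluded, 1)
  expect_false(2 %in% c(spb$train, spb$valid, spb$test))
})

test_that("scaffold grouping agrees with an independent toolkit", {
  # partition agreement (group co-membership), not string equality
  smis <- c("CC(=O)c1ccccc1", "c1ccccc1CCC", "O=C1CCC1C", "CC1CCC1=O",
            "CCCC", "CC(C)CC(C(=O)O)N", "c1ccccc1C(=O)Nc1ccncc1",
            "C1CCCCC1CCc1ccccc1")
  ours <- vapply(smis, murcko_scaffold, character(1))
  script <- paste0(
    "from rdkit import Chem, RDLogger\n",
    "RDLogger.DisableLog('rdApp.*')\n",
    "from rdkit.Chem.Scaffolds import MurckoScaffold\n",
    "smis = ", "['", paste(smis, collapse = "','"), "']\n",
    "for s in smis:\n",
    "    print(MurckoScaffold.MurckoScaffoldSmiles(mol=Chem.MolFromSmiles(s)))")
  theirs <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_length(theirs, length(smis))
  same_group_ours <- outer(ours, ours, "==")
  same_group_theirs <- outer(theirs, theirs, "==")
  expect_equal(unname(same_group_ours), unname(same_group_theirs))
})
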