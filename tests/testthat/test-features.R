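toy_members <- list(glu = c("Map02020", "Map00010"),
                    atp = c("Map00010"),
                    ala = c("Map02020", "Map00625"),
                    gly = character(0))

test_that("pathway variables are the expected 0/1 indicators", {
  pv <- pathway_variables(toy_members, c("Map02020", "Map00625"),
                          c("glu", "atp", "ala", "gly"))
  expect_equal(pv["glu", "Map02020"], 1)
  expect_equal(unname(pv["gly", ]), c(0, 0))       # member of no pathway
  expect_equal(pv["ala", ], c(Map02020 = 1, Map00625 = 1))
  expect_error(pathway_variables(toy_members, character(0), "glu"),
               "non-empty")
})

test_that("metabolites sharing all pathways get identical binary rows", {
  mem <- list(a = c("p1", "p2"), b = c("p1", "p2"))
  pv <- pathway_variables(mem, c("p1", "p2", "p3"), c("a", "b"))
  expect_equal(pv["a", ], pv["b", ])
})

test_that("MPF is the OR of the selected pathway variables", {
  rows <- names(toy_members)
  sel <- c("Map02020", "Map00625")
  mpf <- build_mpf(toy_members, sel, rows)
  pv <- pathway_variables(toy_members, sel, rows)
  expect_equal(unname(mpf), unname(as.numeric(rowSums(pv) > 0)))
  expect_equal(unname(mpf[c("glu", "atp")]), c(1, 0))
  # OR saturation: with every pathway selected, any member maps to 1
  all_pw <- unique(unlist(toy_members))
  mpf_all <- build_mpf(toy_members, all_pw, rows)
  expect_equal(unname(mpf_all), c(1, 1, 1, 0))
  expect_error(build_mpf(toy_members, character(0), rows), "non-empty")
})

make_matrix <- function() {
  set.seed(5)
  X <- cbind(good1 = rnorm(20), good2 = rnorm(20),
             const = rep(2, 20), lowsd = rnorm(20, sd = 1e-4))
  attr(X, "column_origin") <- c(good1 = "molecular", good2 = "molecular",
                                const = "molecular", lowsd = "molecular")
  X
}

test_that("preprocessing drops constant and low-sd descriptors", {
  pr <- preprocess_features(make_matrix())
  expect_setequal(pr$report$removed_constant, "const")
  expect_setequal(pr$report$removed_low_sd, "lowsd")
  expect_setequal(pr$report$kept, c("good1", "good2"))
  expect_setequal(c(pr$report$kept, pr$report$removed_constant,
                    pr$report$removed_low_sd), colnames(make_matrix()))
  expect_error(preprocess_features(make_matrix()[, 3:4]), "every descriptor")
})

test_that("preprocessing is idempotent and keeps origin tags", {
  pr1 <- preprocess_features(make_matrix())
  pr2 <- preprocess_features(pr1$matrix)
  expect_equal(pr2$matrix, pr1$matrix)
  expect_equal(attr(pr1$matrix, "column_origin"),
               c(good1 = "molecular", good2 = "molecular"))
})

test_that("near-constant binary pathway columns are dropped by minority count", {
  X <- cbind(mol = rnorm(30), pw_ok = rep(c(0, 1), 15),
             pw_rare = c(1, rep(0, 29)))
  attr(X, "column_origin") <- c(mol = "molecular", pw_ok = "pathway",
                                pw_rare = "pathway")
  pr <- preprocess_features(X, pathway_min_minority = 2)
  expect_setequal(pr$report$removed_near_constant_pathway, "pw_rare")
  expect_true("pw_ok" %in% pr$report$kept)
})

test_that("feature assembly shares molecular values and splits topology by organism", {
  d <- metabolite_dataset(c("m1", "m2", "m1"), c("eco", "eco", "sce"),
                          neg_log_c = c(1, 2, 3))
  mol <- matrix(c(1, 2, 10, 20), 2, 2,
                dimnames = list(c("m1", "m2"), c("ClogP", "MD001")))
  nets <- list(
    eco = igraph::make_graph(~ m1 - m2 - x1 - m1),  # triangle: cc 1
    sce = igraph::make_graph(~ m1 - z1))
  mem <- list(m1 = "p1", m2 = character(0))
  X <- assemble_features(d, mol, topology = nets, pathway = mem,
                         pathways = c("p1", "p2"))
  expect_equal(rownames(X), c("m1@eco", "m2@eco", "m1@sce"))
  expect_equal(unname(X[c("m1@eco", "m1@sce"), "ClogP"]), c(1, 1))
  expect_equal(unname(X["m1@eco", "Clustering-Coefficient"]), 1)
  expect_equal(unname(X["m1@sce", "Clustering-Coefficient"]), 0)
  expect_equal(unname(X[, "p1"]), c(1, 0, 1))
  org <- attr(X, "column_origin")
  expect_equal(unname(org[c("ClogP", "Degree", "p1")]),
               c("molecular", "topology", "pathway"))
})

test_that("assembly is strict on missing cells and can mean-impute", {
  d <- metabolite_dataset(c("m1", "m2", "m3"), rep("eco", 3), neg_log_c = 1:3)
  mol <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
                dimnames = list(c("m1", "m2", "m3"), c("a", "b")))
  expect_error(assemble_features(d, mol), "missing")
  expect_warning(X <- assemble_features(d, mol, missing = "impute"),
                 "mean-imputed")
  expect_equal(unname(X["m2@eco", "a"]), 2)
})

test_that("CLogP bin report recovers a perfect linear relation", {
  set.seed(9)
  clogp <- runif(60, -6, 0)
  d <- metabolite_dataset(sprintf("m%02d", 1:60), rep("eco", 60),
                          neg_log_c = 2 + 0.5 * clogp)
  names(clogp) <- d$metabolite_id
  rep_ <- clogp_bin_report(d, clogp, bin_width = 0.5)
  expect_equal(rep_$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(sum(rep_$bins$n), 60)
  # bins must follow the fixed-width grid
  expect_true(all(diff(rep_$bins$bin_lower) >= 0.5 - 1e-12))
  expect_error(clogp_bin_report(d, setNames(rep(0.1, 60), d$metabolite_id)),
               "fewer than 3")
})

test_that("pathway deviation table reproduces the packaged reference means", {
  fx <- mpf_deviation_fixture()
  expect_equal(nrow(fx), 14)
  expect_equal(fx$clogp[fx$name == "Glutamate"], -2.69)
  expect_true(is.na(fx$neg_log_c_eco[fx$name == "D-Glucose 6-phosphate"]))
  pd <- pathway_deviation_table(fixture_dataset(), fx$name,
                                setNames(fx$clogp, fx$name))
  expect_equal(round(unname(pd$member_means["mean_clogp"]), 2), -2.98)
  expect_equal(round(unname(pd$member_means["mean_neg_log_c_eco"]), 2), 2.77)
  expect_equal(round(unname(pd$member_means["mean_neg_log_c_sce"]), 2), 2.32)
  expect_equal(sum(!is.na(pd$members$neg_log_c_eco)), 13)
  expect_equal(sum(!is.na(pd$members$neg_log_c_sce)), 11)
})

test_that("pathway deviation table handles a single member", {
  d <- fixture_dataset()
  pd <- pathway_deviation_table(d, "Glutamate", c(Glutamate = -2.69))
  expect_equal(unname(pd$member_means["mean_neg_log_c_eco"]), 1.02)
  expect_equal(unname(pd$member_means["mean_clogp"]), -2.69)
  expect_error(pathway_deviation_table(d, character(0), numeric(0)),
               "non-empty")
})
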