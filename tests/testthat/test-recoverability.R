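variant_a_arrows <- sort(c("X->M_X", "X->M_Y", "X->M_Z",
                       "Z->M_X", "Z->M_Y", "Z->M_Z"))

# estimand checking is internal; exercise it through assess_recoverability
check_estimand_public <- function(g, e)
  assess_recoverability(g, e, case_study_roles())

test_that("estimand constructors enforce role disjointness", {
  expect_error(estimand_regression("Y", "X", c("X", "C")), "covariates")
  expect_error(estimand_regression("Y", "Y"), "differ")
  e <- case_study_estimand()
  expect_identical(e$target, "regression_coefficient")
  expect_error(check_estimand_public(case_study_mdag("a"),
                                     estimand_regression("Y", "X", "M_X")),
               "substantive")
})

test_that("key arrows are extracted through the explicit role map", {
  ka <- extract_key_arrows(case_study_mdag("a"), case_study_roles())
  expect_identical(ka$arrows, variant_a_arrows)
  expect_false(ka$outcome_causes_missingness)
  kb <- extract_key_arrows(case_study_mdag("b"), case_study_roles())
  expect_identical(kb$arrows,
                   sort(c(variant_a_arrows, "Y->M_X", "Y->M_Y", "Y->M_Z")))
  expect_true(kb$outcome_causes_missingness)
})

test_that("complete-confounder arrows are recorded but are not key arrows", {
  g <- case_study_mdag("a")
  g2 <- mdag(unname(g$nodes),
             c(lapply(seq_len(nrow(g$edges)), function(i) g$edges[i, ]),
               list(c("C", "M_X"))))
  ka <- extract_key_arrows(g2, case_study_roles())
  expect_identical(ka$arrows, variant_a_arrows)
  expect_true(any(grepl("C -> M_X", ka$justification)))
})

test_that("a graph with no arrows into indicators yields an empty arrow set", {
  g <- mdag(list(node("X", role = "exposure"), node("Y", role = "outcome"),
                 node("M_X", kind = "missingness", indicator_of = "X")),
            list(c("X", "Y")))
  ka <- extract_key_arrows(g, c(X = "X", Y = "Y", M_X = "M_X"))
  expect_length(ka$arrows, 0)
})

test_that("role maps must be explicit, complete and kind-consistent", {
  g <- case_study_mdag("a")
  r <- case_study_roles()
  expect_error(extract_key_arrows(g, r[names(r) != "M_Z"]),
               "every missingness indicator")
  expect_error(extract_key_arrows(g, r[names(r) != "Y"]), "outcome")
  r_bad <- r; r_bad[["C"]] <- "M_X"; r_bad <- r_bad[names(r_bad) != "M_X"]
  expect_error(extract_key_arrows(g, r_bad), "missingness nodes")
})

test_that("canonical classification maps the study graphs to E and J", {
  la <- classify_canonical(extract_key_arrows(case_study_mdag("a"),
                                              case_study_roles()))
  lb <- classify_canonical(extract_key_arrows(case_study_mdag("b"),
                                              case_study_roles()))
  expect_identical(unclass(la)[1], "E")
  expect_identical(unclass(lb)[1], "J")
})

test_that("non-canonical arrow sets get a signature and a nesting note", {
  k <- structure(list(arrows = sort(c("Z->M_X", "Z->M_Y", "Z->M_Z")),
                      outcome_causes_missingness = FALSE,
                      justification = character(0)),
                 class = "key_arrow_set")
  lab <- classify_canonical(k)
  expect_identical(unclass(lab)[1], "other:Z_all")
  expect_identical(attr(lab, "nested_in"), "E")
  # removing any single key arrow from the E set stays nested in E
  full_e <- variant_a_arrows
  for (drop in full_e) {
    k2 <- structure(list(arrows = setdiff(full_e, drop),
                         outcome_causes_missingness = FALSE,
                         justification = character(0)),
                    class = "key_arrow_set")
    expect_identical(attr(classify_canonical(k2), "nested_in"), "E")
  }
  # an outcome arrow forces nesting under J
  k3 <- structure(list(arrows = c("Y->M_Y"),
                       outcome_causes_missingness = TRUE,
                       justification = character(0)),
                  class = "key_arrow_set")
  expect_identical(attr(classify_canonical(k3), "nested_in"), "J")
})

test_that("catalogue lookup returns the established verdicts", {
  e <- case_study_estimand()
  vE <- lookup_recoverability(structure("E", class = "canonical_label"), e)
  expect_identical(vE$status, "recoverable")
  vJ <- lookup_recoverability(structure("J", class = "canonical_label"), e)
  expect_identical(vJ$status, "not_recoverable")
  expect_error(lookup_recoverability(
    structure("Q", class = "canonical_label"), e), "unknown")
})

test_that("nested labels inherit recoverability; negatives do not propagate", {
  e <- case_study_estimand()
  lab <- structure("other:Z_all", nested_in = "E",
                   class = "canonical_label")
  v <- lookup_recoverability(lab, e)
  expect_identical(v$status, "recoverable")
  expect_true(any(grepl("nesting", v$justification)))
  labj <- structure("other:Y_MY", nested_in = "J",
                    class = "canonical_label")
  expect_identical(lookup_recoverability(labj, e)$status, "undetermined")
})

test_that("uncatalogued estimands return undetermined unless overridden", {
  mm <- estimand_marginal_mean("X", of = "exposure")
  lab <- structure("E", class = "canonical_label")
  expect_identical(lookup_recoverability(lab, mm)$status, "undetermined")
  cat2 <- canonical_catalogue(overrides = data.frame(
    label = "E", estimand = "marginal_mean_exposure",
    status = "recoverable"))
  expect_identical(lookup_recoverability(lab, mm, cat2)$status,
                   "recoverable")
})

test_that("the CRA criterion reproduces both study verdicts and rejects marginal means", {
  e <- case_study_estimand()
  expect_true(cra_valid(case_study_mdag("a"), e)$valid)
  expect_false(cra_valid(case_study_mdag("b"), e)$valid)
  g_mcar <- mdag(list(node("X", role = "exposure"),
                      node("Y", role = "outcome"),
                      node("M_X", kind = "missingness", indicator_of = "X")),
                 list(c("X", "Y")))
  expect_true(cra_valid(g_mcar, estimand_regression("Y", "X"))$valid)
  expect_error(cra_valid(case_study_mdag("a"),
                         estimand_marginal_mean("X")), "marginal means")
})

test_that("catalogue route and CRA criterion agree on the study graphs", {
  e <- case_study_estimand()
  va <- assess_recoverability(case_study_mdag("a"), e, case_study_roles())
  expect_identical(va$status, "recoverable")
  expect_true(va$cra_consistent)
  vb <- assess_recoverability(case_study_mdag("b"), e, case_study_roles())
  expect_identical(vb$status, "not_recoverable")
  expect_false(vb$cra_consistent)
})

test_that("justification trails are byte-identical across reruns", {
  e <- case_study_estimand()
  v1 <- assess_recoverability(case_study_mdag("a"), e, case_study_roles())
  v2 <- assess_recoverability(case_study_mdag("a"), e, case_study_roles())
  expect_identical(v1$justification, v2$justification)
  expect_identical(v1, v2)
})
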