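pg_like_delta <- function() {
  tibble::tibble(transition = "Pr->Pg",
                 bond = square_spec()$bonds,
                 delta_pm = c(-17, 5, -14, 0, 2, 16))
}

test_that("bond orders follow the threshold rule", {
  ref <- setNames(rep(1.42, 6), square_spec()$bonds)
  # zero change: labels from reference alone; 1.42 sits between thresholds
  p0 <- classify_bond_orders(ref, dplyr::mutate(pg_like_delta(), delta_pm = 0))
  expect_true(all(p0$order == "intermediate"))

  p <- classify_bond_orders(ref, pg_like_delta())
  expect_equal(p$predicted_A, 1.42 + pg_like_delta()$delta_pm / 100)
  expect_equal(p$order[1], "double")      # 1.25 A after a -17 pm change
  expect_equal(p$order[6], "single")      # 1.58 A after a +16 pm change
  expect_error(classify_bond_orders(ref, pg_like_delta(),
                                    t_double_A = 1.5, t_single_A = 1.44))
})

test_that("a strong shortening is flagged implausible but still labelled", {
  # the kind of large semi-quantitative change reported for C13-C14
  expect_warning(
    p <- classify_bond_orders(c("C13-C14" = 1.13),
                              tibble::tibble(bond = "C13-C14",
                                             delta_pm = -17)),
    "implausible")
  expect_equal(p$order, "double")
  expect_true(p$implausible)
})

test_that("lowering t_double only demotes doubles to intermediate", {
  # with the rule "length < t_double -> double", shrinking the double window
  # can only turn doubles into intermediates, never mint new doubles
  ref <- setNames(c(1.36, 1.39, 1.42, 1.45, 1.47, 1.50), square_spec()$bonds)
  dl <- dplyr::mutate(pg_like_delta(), delta_pm = 0)
  wide <- classify_bond_orders(ref, dl, t_double_A = 1.43)
  narrow <- classify_bond_orders(ref, dl, t_double_A = 1.38)
  changed <- wide$order != narrow$order
  expect_true(all(wide$order[changed] == "double"))
  expect_true(all(narrow$order[changed] == "intermediate"))
  expect_lte(sum(narrow$order == "double"), sum(wide$order == "double"))
  expect_equal(narrow$order[narrow$order == "single"],
               wide$order[wide$order == "single"])
})

test_that("conjugation extent finds the longest alternating run and rings", {
  topo <- pcb_topology()
  bonds7 <- topo$bonds$bond

  p6 <- order_pattern(c("double", "single", "double", "single",
                        "double", "single"), bonds7[1:6])
  e6 <- conjugation_extent(p6, topo)
  expect_equal(e6$n_alternating_bonds, 6)
  expect_equal(e6$included_rings[[1]], c("C", "D"))

  p4 <- order_pattern(c("double", "single", "double", "single",
                        "single", "single"), bonds7[1:6])
  e4 <- conjugation_extent(p4, topo)
  expect_equal(e4$n_alternating_bonds, 4)
  expect_false("D" %in% e4$included_rings[[1]])

  pint <- order_pattern(rep("intermediate", 6), bonds7[1:6])
  expect_equal(conjugation_extent(pint, topo)$n_alternating_bonds, 0)

  expect_error(conjugation_extent(pint[0, ], topo), "empty")
})

test_that("extent agrees with brute-force enumeration on all 6-chains", {
  # enumerate every {single,double,intermediate}^6 pattern and compare with
  # an independent oracle that scans all O(n^2) windows
  topo <- pcb_topology()
  bonds <- topo$bonds$bond[1:6]
  oracle <- function(lab) {
    best <- 0
    for (i in seq_along(lab)) for (j in i:length(lab)) {
      w <- lab[i:j]
      ok <- !any(w == "intermediate") &&
        (length(w) == 1 || all(w[-1] != w[-length(w)]))
      if (ok) best <- max(best, length(w))
    }
    best
  }
  labels <- c("single", "double", "intermediate")
  grid <- expand.grid(rep(list(labels), 6), stringsAsFactors = FALSE)
  set.seed(3)
  for (row in sample(nrow(grid), 60)) {
    lab <- unlist(grid[row, ], use.names = FALSE)
    got <- conjugation_extent(order_pattern(lab, bonds), topo)
    expect_equal(got$n_alternating_bonds, oracle(lab),
                 info = paste(lab, collapse = ","))
  }
  expect_lte(max(conjugation_extent(order_pattern(
    rep(c("double", "single"), 3), bonds), topo)$n_alternating_bonds), 6)
})

test_that("state comparison flags opposite bonds symmetrically", {
  a <- order_pattern(c("double", "single"), state = "Pg")
  b <- order_pattern(c("single", "double"), state = "Pfr")
  cmp <- compare_states(a, b)
  expect_equal(cmp$fraction_opposite, 1.0)
  expect_equal(compare_states(a, a)$fraction_opposite, 0.0)
  # symmetry of the opposite flags
  expect_equal(tidy(compare_states(b, a))$opposite, tidy(cmp)$opposite)
  expect_error(compare_states(a, order_pattern("single", "C98-C99")),
               "no bonds")
})

test_that("antagonistic predicted patterns classify as opposite", {
  # two transitions with sign-flipped bond changes around a neutral reference
  ref <- setNames(rep(1.42, 6), square_spec()$bonds)
  dl_pg <- pg_like_delta()
  dl_pfr <- dplyr::mutate(dl_pg, transition = "Pr->Pfr",
                          delta_pm = -delta_pm)
  pg <- classify_bond_orders(ref, dl_pg)
  pfr <- classify_bond_orders(ref, dl_pfr)
  cmp <- compare_states(pg, pfr)
  both_classified <- pg$order != "intermediate" & pfr$order != "intermediate"
  expect_true(all(tidy(cmp)$opposite[both_classified]))
  expect_equal(glance(cmp)$n_opposite, sum(both_classified))
})

test_that("the conjugation report JSON bundles states and antagonism", {
  ref <- setNames(rep(1.42, 6), square_spec()$bonds)
  pg <- classify_bond_orders(ref, pg_like_delta())
  pfr <- classify_bond_orders(ref, dplyr::mutate(pg_like_delta(),
                                                 transition = "Pr->Pfr",
                                                 delta_pm = -delta_pm))
  path <- withr::local_tempfile(fileext = ".json")
  write_conjugation_report(list(Pg = pg, Pfr = pfr),
                           compare_states(pg, pfr),
                           subset_topology(pcb_topology(),
                                           square_spec()$bonds),
                           path)
  rep_ <- jsonlite::fromJSON(path)
  expect_named(rep_$states, c("Pg", "Pfr"))
  expect_equal(rep_$antagonism$fraction_opposite,
               compare_states(pg, pfr)$fraction_opposite)
})
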