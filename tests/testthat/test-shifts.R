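# Chemical-shift comparison: RMSD to random coil, rank correlation against
# model predictions, and the cross-model verdict table.

mk_shifts <- function(residues, atoms, values, source = NULL) {
  g <- expand.grid(atom = atoms, residue = residues, stringsAsFactors = FALSE)
  data.frame(residue = g$residue, residue_type = "ALA", atom = g$atom,
             shift_ppm = values)
}

test_that("coil RMSD computes paired root-mean-square differences with selection", {
  atoms <- c("N", "H", "CA", "CB")
  exp_tab <- mk_shifts(1:2, atoms, c(120, 8.2, 55, 30, 118, 8.0, 54, 29))
  coil <- exp_tab
  coil$shift_ppm <- coil$shift_ppm + c(0.3, -0.3, 0.3, -0.3, 0.3, -0.3, 0.3, -0.3)
  r <- coil_rmsd(exp_tab, coil, residues = 1:2, atoms = atoms)
  expect_equal(r$rmsd, 0.3, tolerance = 1e-12)
  expect_equal(r$n_pairs, 8)
  expect_equal(coil_rmsd(exp_tab, exp_tab)$rmsd, 0)
  ## atom selection changes the pair count, both reported
  rn <- coil_rmsd(exp_tab, coil, atoms = "N")
  expect_equal(rn$n_pairs, 2)
  ## row order and sign symmetry
  r2 <- coil_rmsd(exp_tab[sample(8), ], coil, atoms = atoms)
  expect_equal(r2$rmsd, r$rmsd)
  expect_error(coil_rmsd(exp_tab, coil, residues = 50:60), "no matched")
})

test_that("rank correlation matches a brute-force mid-rank implementation", {
  spearman_brute <- function(x, y) {
    midrank <- function(v) {
      sapply(seq_along(v), function(i) {
        sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
      })
    }
    rx <- midrank(x); ry <- midrank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  exp_tab <- mk_shifts(1:20, "N", 100 + 1:20)
  pred <- exp_tab
  expect_equal(model_correlation(exp_tab, pred)$rho, 1)
  rev_tab <- pred
  rev_tab$shift_ppm <- rev(rev_tab$shift_ppm)
  expect_equal(model_correlation(exp_tab, rev_tab)$rho, -1)
  ## one swapped pair and ties: compare against the brute-force oracle
  set.seed(3)
  for (i in 1:5) {
    pred2 <- pred
    pred2$shift_ppm <- pred$shift_ppm + rnorm(20, 0, 2)
    pred2$shift_ppm[c(4, 5)] <- pred2$shift_ppm[c(5, 4)]
    pred2$shift_ppm[7] <- pred2$shift_ppm[8] # tie
    got <- model_correlation(exp_tab, pred2)
    expect_equal(got$rho, spearman_brute(exp_tab$shift_ppm, pred2$shift_ppm),
                 tolerance = 1e-12)
    expect_equal(got$n_pairs, 20)
  }
  ## constant predictions are flagged, not silently correlated
  const <- pred
  const$shift_ppm <- 5
  expect_true(is.na(model_correlation(exp_tab, const)$rho))
  expect_error(model_correlation(exp_tab[1:2, ], pred[1:2, ]), "3 matched")
})

test_that("model ranking picks the generating structure and reports ties", {
  set.seed(11)
  base <- mk_shifts(1:25, "N", runif(25, 105, 130))
  model_a <- base
  model_b <- base
  model_b$shift_ppm <- base$shift_ppm + rnorm(25, 0, 4) # decorrelated
  experimental <- base
  experimental$shift_ppm <- base$shift_ppm + rnorm(25, 0, 0.3)
  predicted <- list(
    A = list(p1 = model_a, p2 = model_a),
    B = list(p1 = model_b, p2 = model_b)
  )
  rk <- rank_models(list(Ground = experimental), predicted)
  expect_equal(rk$verdict$best_model, "A")
  expect_equal(nrow(rk$table), 4)
  ## verdict invariant under predictor relabeling
  predicted_swapped <- list(
    A = list(p2 = model_a, p1 = model_a),
    B = list(p2 = model_b, p1 = model_b)
  )
  rk2 <- rank_models(list(Ground = experimental), predicted_swapped)
  expect_equal(rk2$verdict$best_model, "A")
  ## identical models tie, no silent winner
  rk3 <- rank_models(list(Ground = experimental),
                     list(A = list(p1 = model_a), B = list(p1 = model_a)))
  expect_equal(rk3$verdict$best_model, "tie")
  ## missing combinations are NA cells, verdict from the rest
  rk4 <- rank_models(list(Ground = experimental),
                     list(A = list(p1 = model_a), B = list(p2 = model_b)))
  expect_true(any(is.na(rk4$table$rho)))
})

test_that("the minimal NMR-STAR reader extracts assigned shifts", {
  star <- c(
    "data_shifts",
    "save_assigned_chemical_shifts",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  1 52 HIS N 118.32",
    "  2 52 HIS H 8.11",
    "  3 53 LEU CA 55.02",
    "stop_",
    "save_"
  )
  path <- tempfile(fileext = ".str")
  writeLines(star, path)
  tab <- read_nmrstar_shifts(path)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$residue, c(52, 52, 53))
  expect_equal(tab$atom, c("N", "H", "CA"))
  expect_equal(tab$shift_ppm[1], 118.32)
  ## delimited reader round trip with atom normalization
  tsv <- tempfile(fileext = ".tsv")
  out <- data.frame(residue = 1:2, residue_type = "GLY",
                    atom = c("Ca", "cb"), shift_ppm = c(45.1, 0))
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_shift_table(tsv)
  expect_equal(got$atom, c("CA", "CB"))
})
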