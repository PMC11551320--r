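## Stage 5: chemical-shift-based characterization of states — RMSD against
## random-coil predictions and rank correlation of experimental vs
## model-predicted shifts to discriminate structural models.

normalize_atom <- function(atom) {
  atom <- toupper(trimws(atom))
  map <- c("CA" = "CA", "CΑ" = "CA", "CALPHA" = "CA",
           "CB" = "CB", "CBETA" = "CB", "CG" = "CG", "CGAMMA" = "CG",
           "CD" = "CD", "CDELTA" = "CD", "HN" = "H", "H" = "H", "N" = "N",
           "C" = "C", "HA" = "HA")
  ifelse(atom %in% names(map), map[atom], atom)
}

#' Read a delimited chemical-shift table
#'
#' Expects columns `residue`, `residue_type` (optional), `atom`, `shift_ppm`
#' and optionally `source`. Atom names are normalized (e.g. `Ca`/`CALPHA` to
#' `CA`).
#'
#' @param path Path to a tab- or comma-separated file with a header.
#' @return Data frame with normalized atom names.
#' @export
read_shift_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("residue", "atom", "shift_ppm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("shift table missing column(s): ", paste(miss, collapse = ", "))
  tab$atom <- normalize_atom(tab$atom)
  if (any(!is.finite(tab$shift_ppm))) stop("non-finite shift values in ", path)
  tab
}

#' Minimal NMR-STAR chemical-shift reader
#'
#' Extracts `(residue, residue type, atom, shift)` rows from the
#' `_Atom_chem_shift` loop of an NMR-STAR 3 file. This is a deliberately small
#' reader for assigned-chemical-shift deposits only, not a general STAR
#' parser.
#'
#' @param path Path to an NMR-STAR file.
#' @return Data frame with `residue`, `residue_type`, `atom`, `shift_ppm`.
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    ## collect the tag block directly after loop_
    i <- ls + 1
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    cols <- sub("^_Atom_chem_shift\\.", "", tags)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" ) { i <- i + 1; next }
      if (ln == "stop_" || startsWith(ln, "loop_") || startsWith(ln, "save_")) break
      rows[[length(rows) + 1]] <- strsplit(ln, "\\s+")[[1]]
      i <- i + 1
    }
    mat <- do.call(rbind, rows)
    if (is.null(mat) || ncol(mat) != length(cols)) {
      stop("malformed _Atom_chem_shift loop in ", path)
    }
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols
    seq_col <- intersect(c("Seq_ID", "Comp_index_ID"), cols)[1]
    return(data.frame(
      residue = as.integer(df[[seq_col]]),
      residue_type = df[["Comp_ID"]],
      atom = normalize_atom(df[["Atom_ID"]]),
      shift_ppm = as.numeric(df[["Val"]])
    ))
  }
  stop("no _Atom_chem_shift loop found in ", path)
}

match_shifts <- function(a, b, residues = NULL, atoms = NULL) {
  if (!is.null(atoms)) {
    atoms <- normalize_atom(atoms)
    a <- a[a$atom %in% atoms, ]
    b <- b[b$atom %in% atoms, ]
  }
  if (!is.null(residues)) {
    a <- a[a$residue %in% residues, ]
    b <- b[b$residue %in% residues, ]
  }
  m <- merge(a[, c("residue", "atom", "shift_ppm")],
             b[, c("residue", "atom", "shift_ppm")],
             by = c("residue", "atom"), suffixes = c("_a", "_b"))
  m
}

#' RMSD between matched chemical shifts
#'
#' Root-mean-square difference over matched `(residue, atom)` pairs within a
#' residue range and atom selection; used e.g. to compare an experimental
#' state against random-coil predictions.
#'
#' @param experimental,reference Shift tables (data frames with `residue`,
#'   `atom`, `shift_ppm`).
#' @param residues Integer vector of residue numbers to include (inclusive
#'   range expanded by the caller), or `NULL` for all.
#' @param atoms Atom-name selection (e.g. `c("N", "H", "CA", "CB")`), or
#'   `NULL` for all.
#' @return List with `rmsd` (ppm) and `n_pairs`.
#' @export
coil_rmsd <- function(experimental, reference, residues = NULL, atoms = NULL) {
  m <- match_shifts(experimental, reference, residues, atoms)
  if (nrow(m) == 0) {
    stop("no matched (residue, atom) pairs for residues = ",
         if (is.null(residues)) "<all>" else paste(range(residues), collapse = "-"),
         ", atoms = ", if (is.null(atoms)) "<all>" else paste(atoms, collapse = ","))
  }
  d <- m$shift_ppm_a - m$shift_ppm_b
  list(rmsd = sqrt(mean(d^2)), n_pairs = nrow(m))
}

#' Rank correlation of experimental vs predicted shifts
#'
#' Spearman rank correlation (ties mid-ranked) over matched
#' `(residue, atom)` pairs.
#'
#' @inheritParams coil_rmsd
#' @param predicted Predicted shift table.
#' @return List with `rho`, `n_pairs`; `rho` is `NA` (flagged via attribute
#'   `"degenerate"`) if either matched vector is constant.
#' @export
model_correlation <- function(experimental, predicted, residues = NULL,
                              atoms = NULL) {
  m <- match_shifts(experimental, predicted, residues, atoms)
  if (nrow(m) < 3) stop("need at least 3 matched pairs (got ", nrow(m), ")")
  if (stats::sd(m$shift_ppm_b) == 0 || stats::sd(m$shift_ppm_a) == 0) {
    rho <- NA_real_
    attr(rho, "degenerate") <- TRUE
    return(list(rho = rho, n_pairs = nrow(m)))
  }
  rho <- stats::cor(m$shift_ppm_a, m$shift_ppm_b, method = "spearman")
  list(rho = rho, n_pairs = nrow(m))
}

#' Cross-table of state/model/predictor correlations and best-model verdicts
#'
#' For every combination of experimental state, structural model and shift
#' predictor, computes the Spearman correlation between experimental and
#' predicted shifts; per state and predictor the best model is the argmax
#' correlation, and the per-state verdict is the majority best model across
#' predictors (ties reported as `"tie"`).
#'
#' @param experimental Named list of shift tables, one per experimental state.
#' @param predicted Nested named list: `predicted[[model]][[predictor]]` is a
#'   shift table.
#' @param residues,atoms Optional selections as in [coil_rmsd()].
#' @return List with `table` (state, model, predictor, rho, n_pairs; absent
#'   combinations marked by `NA`) and `verdict` (state, best_model).
#' @export
rank_models <- function(experimental, predicted, residues = NULL, atoms = NULL) {
  stopifnot(length(predicted) >= 2)
  predictors <- unique(unlist(lapply(predicted, names)))
  grid <- expand.grid(
    state = names(experimental), model = names(predicted),
    predictor = predictors, stringsAsFactors = FALSE
  )
  grid$rho <- NA_real_
  grid$n_pairs <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    pred <- predicted[[grid$model[i]]][[grid$predictor[i]]]
    if (is.null(pred)) next
    mc <- tryCatch(
      model_correlation(experimental[[grid$state[i]]], pred, residues, atoms),
      error = function(e) NULL
    )
    if (!is.null(mc)) {
      grid$rho[i] <- mc$rho
      grid$n_pairs[i] <- mc$n_pairs
    }
  }
  verdict <- do.call(rbind, lapply(names(experimental), function(st) {
    sub <- grid[grid$state == st & !is.na(grid$rho), ]
    wins <- vapply(split(sub, sub$predictor), function(s) {
      top <- s$model[s$rho == max(s$rho)]
      if (length(top) > 1) "tie" else top
    }, "")
    wins <- wins[wins != "tie"]
    best <- if (length(wins) == 0) {
      "tie"
    } else {
      tb <- sort(table(wins), decreasing = TRUE)
      if (length(tb) > 1 && tb[1] == tb[2]) "tie" else names(tb)[1]
    }
    data.frame(state = st, best_model = best)
  }))
  list(table = grid, verdict = verdict)
}
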