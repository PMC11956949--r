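# Elemental-composition mass arithmetic and the two custom azido-glycan
# (GalNAz) modification definitions used for open-modification searching.

# Monoisotopic atomic masses (Da). Pinned to >= 7 significant figures so
# 4-decimal reproduction of modification delta masses is stable.
MONOISOTOPIC_MASSES <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740,
  O = 15.9949146,
  S = 31.97207117
)

#' Parse a molecular formula into an elemental composition
#'
#' Accepts a compact formula such as `"C8H12N4O5"` (or a named numeric vector
#' of atom counts) and returns a named integer vector of counts per element.
#' Only C, H, N, O and S are supported; these cover glycans, peptides and the
#' click-chemistry reporter reagents handled here.
#'
#' @param x A formula string like `"C8H12N4O5"`, or a named numeric vector of
#'   nonnegative atom counts.
#' @return Named integer vector of atom counts, one entry per element present.
#' @examples
#' elemental_composition("H2O")
#' elemental_composition("C8H12N4O5")
#' @export
elemental_composition <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    if (is.null(names(counts)) || any(names(counts) == "")) {
      abort("Numeric compositions must be fully named by element symbol.")
    }
  } else if (is.character(x) && length(x) == 1) {
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", x)) {
      abort(sprintf("Cannot parse molecular formula: '%s'.", x))
    }
    m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
    tokens <- regmatches(x, list(m))[[1]]
    elems <- sub("[0-9]*$", "", tokens)
    nums <- sub("^[A-Za-z]+", "", tokens)
    counts <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
    names(counts) <- elems
    counts <- tapply(counts, names(counts), sum)
    counts <- counts[order(names(counts))]
  } else {
    abort("`x` must be a formula string or a named numeric vector.")
  }
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASSES))
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown element symbol(s): %s (supported: %s).",
      paste(unknown, collapse = ", "),
      paste(names(MONOISOTOPIC_MASSES), collapse = ", ")
    ))
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("Atom counts must be nonnegative integers.")
  }
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[out > 0 | length(out) == 0]
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums atom counts times standard monoisotopic atomic masses
#' (C = 12 exactly, H = 1.0078250319, N = 14.0030740, O = 15.9949146,
#' S = 31.97207117 Da).
#'
#' @param composition A formula string or named count vector, passed through
#'   [elemental_composition()].
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.0106
#' monoisotopic_mass("C8H12N4O5")  # 244.0808, the GalNAz glycan residue
#' @export
monoisotopic_mass <- function(composition) {
  comp <- elemental_composition(composition)
  if (length(comp) == 0) {
    return(0)
  }
  sum(comp * MONOISOTOPIC_MASSES[names(comp)])
}

#' Combine two elemental compositions
#'
#' Element-wise sum of atom counts. The copper-catalysed azide-alkyne
#' cycloaddition conserves all atoms of both reactants, so the clicked
#' adduct's composition is exactly `compose_composition(glycan, reagent)`.
#'
#' @param a,b Compositions (formula strings or named count vectors).
#' @return Named integer vector of summed atom counts.
#' @export
compose_composition <- function(a, b) {
  ca <- elemental_composition(a)
  cb <- elemental_composition(b)
  elems <- sort(union(names(ca), names(cb)))
  out <- vapply(
    elems,
    function(e) sum(ca[e], cb[e], na.rm = TRUE),
    integer(1)
  )
  out[out > 0 | length(out) == 0]
}

#' Custom azido-glycan modification specifications
#'
#' The two serine/threonine modifications searched for metabolically labeled
#' newsECM glycoproteins: the bare GalNAz glycan residue (an N-acetyl
#' hexosamine residue whose acetyl bears an azide, C8H12N4O5, +244.0808 Da)
#' and the same residue after click conjugation with
#' alkyne-PEG4-desthiobiotin (C21H37N3O6), giving C29H49N7O11, +671.3490 Da.
#'
#' @return A tibble with one row per modification: `name`, `target_residues`,
#'   `composition` (formula string) and `delta_mass` (monoisotopic Da).
#' @examples
#' modification_specs()
#' @export
modification_specs <- function() {
  galnaz <- "C8H12N4O5"
  reagent <- "C21H37N3O6"
  clicked <- compose_composition(galnaz, reagent)
  clicked_formula <- paste0(names(clicked), clicked, collapse = "")
  specs <- tibble::tibble(
    name = c(
      "GalNAz glycan on S/T",
      "GalNAz glycan + alkyne-PEG4-desthiobiotin on S/T"
    ),
    target_residues = list(c("S", "T"), c("S", "T")),
    composition = c(galnaz, clicked_formula),
    delta_mass = c(monoisotopic_mass(galnaz), monoisotopic_mass(clicked))
  )
  # invariant: printed delta masses derive from the compositions
  stopifnot(all(abs(
    specs$delta_mass -
      vapply(specs$composition, monoisotopic_mass, numeric(1))
  ) < 5e-5))
  specs
}

#' Format modification specs as a search-engine custom-modification block
#'
#' Renders [modification_specs()] (or any tibble of the same shape) as plain
#' text lines, one per modification, suitable for pasting into a search
#' engine's custom-modification configuration.
#'
#' @param specs Tibble as returned by [modification_specs()].
#' @return Character vector of formatted lines.
#' @export
format_modification_specs <- function(specs = modification_specs()) {
  vapply(
    seq_len(nrow(specs)),
    function(i) {
      sprintf(
        "%s\tresidues=%s\tcomposition=%s\tmonoisotopic=%.4f",
        specs$name[i],
        paste(specs$target_residues[[i]], collapse = ","),
        specs$composition[i],
        specs$delta_mass[i]
      )
    },
    character(1)
  )
}
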