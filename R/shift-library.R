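#' Construct a ShiftRecord
#'
#' @param moleculeId unique molecule identifier.
#' @param carbonShifts,protonShifts numeric ppm vectors (either may be empty,
#'   not both). Every nucleus is listed individually; equivalent nuclei are
#'   not collapsed.
#' @param smiles optional SMILES string (informational).
#' @return A [ShiftRecord-class] object.
#' @examples
#' shiftRecord("m1", carbonShifts = c(10, 20, 30), protonShifts = c(1.2, 3.4))
#' @export
shiftRecord <- function(moleculeId, carbonShifts = numeric(),
                        protonShifts = numeric(), smiles = NA_character_) {
  new("ShiftRecord", moleculeId = as.character(moleculeId),
      smiles = as.character(smiles),
      carbonShifts = as.numeric(carbonShifts),
      protonShifts = as.numeric(protonShifts))
}

#' Construct a ShiftLibrary
#'
#' @param records list of [ShiftRecord-class] objects, order preserved.
#' @param solvent solvent label for the whole library.
#' @return A [ShiftLibrary-class] object.
#' @examples
#' lib <- shiftLibrary(list(
#'   shiftRecord("m1", c(10, 20, 30), c(1.2, 3.4)),
#'   shiftRecord("m2", c(100))))
#' nMolecules(lib)
#' @export
shiftLibrary <- function(records, solvent = "unspecified") {
  if (length(records) == 0L) stop("library must contain at least one molecule")
  ok <- vapply(records, is, logical(1), class2 = "ShiftRecord")
  if (!all(ok)) stop("all records must be ShiftRecord objects")
  new("ShiftLibrary",
      ids = vapply(records, slot, character(1), name = "moleculeId"),
      smiles = vapply(records, slot, character(1), name = "smiles"),
      carbonShifts = lapply(records, slot, name = "carbonShifts"),
      protonShifts = lapply(records, slot, name = "protonShifts"),
      solvent = as.character(solvent))
}

#' Accessors for ShiftLibrary
#'
#' `moleculeIds` returns the molecule identifiers in input order;
#' `carbonShifts`/`protonShifts` return the per-molecule shift lists (or a
#' single molecule's vector when `id` is given); `solventLabel` the solvent
#' tag; `nMolecules` the number of records.
#'
#' @param x a [ShiftLibrary-class].
#' @param id optional molecule id selecting a single record.
#' @param ... unused.
#' @name ShiftLibrary-accessors
NULL

#' @rdname ShiftLibrary-accessors
#' @export
setMethod("moleculeIds", "ShiftLibrary", function(x) x@ids)

.lookupIdx <- function(x, id) {
  i <- match(id, x@ids)
  if (anyNA(i)) stop("unknown molecule_id: ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' @rdname ShiftLibrary-accessors
#' @export
setMethod("carbonShifts", "ShiftLibrary", function(x, id = NULL) {
  if (is.null(id)) setNames(x@carbonShifts, x@ids)
  else if (length(id) == 1L) x@carbonShifts[[.lookupIdx(x, id)]]
  else setNames(x@carbonShifts[.lookupIdx(x, id)], id)
})

#' @rdname ShiftLibrary-accessors
#' @export
setMethod("protonShifts", "ShiftLibrary", function(x, id = NULL) {
  if (is.null(id)) setNames(x@protonShifts, x@ids)
  else if (length(id) == 1L) x@protonShifts[[.lookupIdx(x, id)]]
  else setNames(x@protonShifts[.lookupIdx(x, id)], id)
})

#' @rdname ShiftLibrary-accessors
#' @export
setMethod("solventLabel", "ShiftLibrary", function(x) x@solvent)

#' @rdname ShiftLibrary-accessors
#' @export
setMethod("nMolecules", "ShiftLibrary", function(x) length(x@ids))

#' Retrieve one molecule as a ShiftRecord
#'
#' @param lib a [ShiftLibrary-class].
#' @param id molecule identifier.
#' @return A [ShiftRecord-class].
#' @export
getRecord <- function(lib, id) {
  i <- .lookupIdx(lib, id)
  new("ShiftRecord", moleculeId = lib@ids[i], smiles = lib@smiles[i],
      carbonShifts = lib@carbonShifts[[i]], protonShifts = lib@protonShifts[[i]])
}

#' Per-molecule nucleus counts
#'
#' @param x a [ShiftLibrary-class].
#' @return data.frame with columns `molecule_id`, `nC`, `nH` in record order.
#' @export
setMethod("nucleusCounts", "ShiftLibrary", function(x) {
  data.frame(molecule_id = x@ids,
             nC = lengths(x@carbonShifts),
             nH = lengths(x@protonShifts),
             row.names = NULL)
})

#' Count index of a library
#'
#' Maps each observed (carbon count, hydrogen count) pair, keyed as
#' `"<nC>_<nH>"`, to the molecule ids with exactly those counts. Derived from
#' the shift lists, so it is always consistent with the records.
#'
#' @param x a [ShiftLibrary-class].
#' @return named list of character vectors.
#' @export
setMethod("countIndex", "ShiftLibrary", function(x) {
  key <- countKey(lengths(x@carbonShifts), lengths(x@protonShifts))
  split(x@ids, key)
})

#' Summarize a shift library
#'
#' Totals of molecules and of carbon/hydrogen nuclei, plus the per-molecule
#' count histograms (molecules per given number of carbons / hydrogens).
#'
#' @param x a [ShiftLibrary-class].
#' @return A [LibrarySummary-class].
#' @export
setMethod("summarizeLibrary", "ShiftLibrary", function(x) {
  nc <- lengths(x@carbonShifts); nh <- lengths(x@protonShifts)
  tabulate_named <- function(v) {
    t <- table(v)
    setNames(as.integer(t), names(t))
  }
  new("LibrarySummary",
      nMolecules = length(x@ids),
      nCarbonNuclei = as.integer(sum(nc)),
      nHydrogenNuclei = as.integer(sum(nh)),
      carbonHist = tabulate_named(nc),
      protonHist = tabulate_named(nh))
})

setMethod("show", "ShiftRecord", function(object) {
  cat("ShiftRecord", object@moleculeId,
      sprintf("(%d 13C, %d 1H shifts)\n",
              length(object@carbonShifts), length(object@protonShifts)))
})

setMethod("show", "ShiftLibrary", function(object) {
  cat(sprintf("ShiftLibrary: %d molecules, solvent '%s'\n",
              length(object@ids), object@solvent))
  cat(sprintf("  %d carbon and %d hydrogen nuclei in total\n",
              sum(lengths(object@carbonShifts)),
              sum(lengths(object@protonShifts))))
})

setMethod("show", "LibrarySummary", function(object) {
  cat(sprintf("LibrarySummary: %d molecules (%d carbon, %d hydrogen nuclei)\n",
              object@nMolecules, object@nCarbonNuclei, object@nHydrogenNuclei))
})
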