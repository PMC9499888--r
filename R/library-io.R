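# Readers/writers for shift libraries.
#
# Canonical CSV is long format: one row per nucleus with columns
# molecule_id, solvent, nucleus ("13C" or "1H"), shift_ppm and an optional
# smiles column. Canonical JSON is one object per molecule with two shift
# arrays under a top-level solvent label. Both serialize doubles at full
# precision so a write/read cycle is bit-exact.

.NUCLEI <- c("13C", "1H")

.applyConverter <- function(x, conv) {
  if (is.null(conv)) return(x)
  conv[["slope"]] * x + conv[["intercept"]]
}

.checkConverter <- function(converter) {
  if (is.null(converter)) return(invisible(NULL))
  for (nm in names(converter)) {
    if (!nm %in% c("carbon", "proton"))
      stop("converter entries must be named 'carbon' and/or 'proton'")
    cv <- converter[[nm]]
    if (!is.list(cv) && !is.numeric(cv))
      stop("each converter must supply slope and intercept")
    if (!all(c("slope", "intercept") %in% names(cv)))
      stop("each converter must supply slope and intercept")
  }
  invisible(NULL)
}

#' Read a shift library
#'
#' Ingests a reference library of per-molecule \eqn{^{13}}C and \eqn{^1}H
#' chemical shift lists from one of the supported formats:
#' \describe{
#'   \item{`"csv"`}{canonical long CSV (`molecule_id`, `solvent`, `nucleus`,
#'     `shift_ppm`, optional `smiles`); record order is the order of first
#'     appearance.}
#'   \item{`"json"`}{canonical JSON: top-level `solvent` plus a `molecules`
#'     array of objects with `molecule_id`, optional `smiles`,
#'     `carbon_shifts`, `proton_shifts`.}
#'   \item{`"moldir"`}{a directory holding one `.mol` file per molecule
#'     (pass-through, optional) plus a tab-separated `shifts.tsv` with
#'     columns `molecule_id`, `nucleus`, `shift_ppm`.}
#' }
#'
#' Shifts are expected already referenced to ppm. When raw values need an
#' affine re-referencing, supply `converter`, e.g.
#' `list(carbon = c(slope = -1, intercept = 186.4))`; each shift becomes
#' `slope * value + intercept` at read time.
#'
#' @param path file (csv/json) or directory (moldir).
#' @param format one of "csv", "json", "moldir".
#' @param converter optional per-nucleus affine conversion (see Details).
#' @return A [ShiftLibrary-class].
#' @export
readShiftLibrary <- function(path, format = c("csv", "json", "moldir"),
                             converter = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such path: ", path)
  .checkConverter(converter)
  switch(format,
         csv = .readCsvLibrary(path, converter),
         json = .readJsonLibrary(path, converter),
         moldir = .readMolDirLibrary(path, converter))
}

.assembleLibrary <- function(ids_long, nucleus, shift, solvent,
                             smiles_long = NULL, context = NULL) {
  bad <- !is.finite(shift)
  if (any(bad)) {
    where <- if (is.null(context)) which(bad)[1L] else context[bad][1L]
    stop("non-numeric or non-finite shift value at row ", where,
         " (molecule_id ", ids_long[bad][1L], ")")
  }
  if (!all(nucleus %in% .NUCLEI))
    stop("nucleus column must be one of: ", paste(.NUCLEI, collapse = ", "),
         " (got '", setdiff(unique(nucleus), .NUCLEI)[1L], "')")
  ids <- unique(ids_long)
  f <- factor(ids_long, levels = ids)
  cs <- split(shift[nucleus == "13C"], f[nucleus == "13C"])
  hs <- split(shift[nucleus == "1H"], f[nucleus == "1H"])
  smiles <- rep(NA_character_, length(ids))
  if (!is.null(smiles_long)) {
    first <- !duplicated(ids_long)
    smiles <- as.character(smiles_long[first])
    smiles[!nzchar(smiles) | is.na(smiles)] <- NA_character_
  }
  new("ShiftLibrary", ids = ids, smiles = smiles,
      carbonShifts = lapply(cs, as.numeric),
      protonShifts = lapply(hs, as.numeric),
      solvent = solvent)
}

.convertLong <- function(shift, nucleus, converter) {
  if (is.null(converter)) return(shift)
  if (!is.null(converter$carbon)) {
    i <- nucleus == "13C"
    shift[i] <- .applyConverter(shift[i], converter$carbon)
  }
  if (!is.null(converter$proton)) {
    i <- nucleus == "1H"
    shift[i] <- .applyConverter(shift[i], converter$proton)
  }
  shift
}

.readCsvLibrary <- function(path, converter) {
  df <- read.csv(path, colClasses = "character", check.names = TRUE)
  need <- c("molecule_id", "solvent", "nucleus", "shift_ppm")
  if (!all(need %in% names(df)))
    stop("canonical CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty library: no rows in ", path)
  shift <- suppressWarnings(as.numeric(df$shift_ppm))
  if (anyNA(shift)) {
    row <- which(is.na(shift))[1L]
    stop("non-numeric shift '", df$shift_ppm[row], "' at data row ", row,
         " (molecule_id ", df$molecule_id[row], ")")
  }
  shift <- .convertLong(shift, df$nucleus, converter)
  solvent <- unique(df$solvent)
  if (length(solvent) != 1L)
    stop("canonical CSV must carry a single solvent label, found: ",
         paste(solvent, collapse = ", "))
  .assembleLibrary(df$molecule_id, df$nucleus, shift, solvent,
                   smiles_long = df[["smiles"]])
}

.readJsonLibrary <- function(path, converter) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$molecules) || length(obj$molecules) == 0L)
    stop("empty library: no molecules in ", path)
  ids <- vapply(obj$molecules, function(m) as.character(m$molecule_id %||% NA),
                character(1))
  if (anyNA(ids)) stop("molecule without molecule_id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate molecule_id: ", ids[duplicated(ids)][1L])
  toNum <- function(v, id) {
    x <- suppressWarnings(as.numeric(unlist(v, use.names = FALSE)))
    if (anyNA(x)) stop("non-numeric shift for molecule_id ", id)
    x
  }
  cs <- lapply(obj$molecules, function(m)
    toNum(m$carbon_shifts, m$molecule_id))
  hs <- lapply(obj$molecules, function(m)
    toNum(m$proton_shifts, m$molecule_id))
  if (!is.null(converter$carbon))
    cs <- lapply(cs, .applyConverter, conv = converter$carbon)
  if (!is.null(converter$proton))
    hs <- lapply(hs, .applyConverter, conv = converter$proton)
  smiles <- vapply(obj$molecules, function(m) {
    s <- m$smiles
    if (is.null(s) || !nzchar(s)) NA_character_ else as.character(s)
  }, character(1))
  new("ShiftLibrary", ids = ids, smiles = smiles,
      carbonShifts = cs, protonShifts = hs,
      solvent = as.character(obj$solvent %||% "unspecified"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# MOL directory + shift table, mirroring a structure-files-plus-DFT-shifts
# distribution. Only shifts.tsv is parsed; .mol files are pass-through
# structure data and merely checked for presence when listed.
.readMolDirLibrary <- function(path, converter) {
  if (!dir.exists(path)) stop("moldir format expects a directory: ", path)
  tsv <- file.path(path, "shifts.tsv")
  if (!file.exists(tsv)) stop("missing shift table: ", tsv)
  df <- read.csv(tsv, sep = "\t", colClasses = "character")
  need <- c("molecule_id", "nucleus", "shift_ppm")
  if (!all(need %in% names(df)))
    stop("shifts.tsv must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty library: no rows in ", tsv)
  shift <- suppressWarnings(as.numeric(df$shift_ppm))
  if (anyNA(shift)) {
    row <- which(is.na(shift))[1L]
    stop("non-numeric shift '", df$shift_ppm[row], "' at data row ", row,
         " (molecule_id ", df$molecule_id[row], ")")
  }
  shift <- .convertLong(shift, df$nucleus, converter)
  solvent <- basename(normalizePath(path))
  .assembleLibrary(df$molecule_id, df$nucleus, shift, solvent)
}

#' Write a shift library
#'
#' Serializes to the canonical CSV or JSON layout (see [readShiftLibrary()]).
#' Doubles are written with 17 significant digits so that
#' `readShiftLibrary(writeShiftLibrary(lib, p), ...)` reproduces `lib`
#' exactly, bit for bit.
#'
#' @param lib a valid [ShiftLibrary-class].
#' @param path output file.
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @export
writeShiftLibrary <- function(lib, path, format = c("csv", "json")) {
  format <- match.arg(format)
  validObject(lib)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (format == "csv") .writeCsvLibrary(lib, path) else .writeJsonLibrary(lib, path)
  invisible(path)
}

.fullPrec <- function(x) sprintf("%.17g", x)

.writeCsvLibrary <- function(lib, path) {
  n_c <- lengths(lib@carbonShifts); n_h <- lengths(lib@protonShifts)
  ids <- c(rep(lib@ids, n_c), rep(lib@ids, n_h))
  smi <- c(rep(lib@smiles, n_c), rep(lib@smiles, n_h))
  nuc <- c(rep("13C", sum(n_c)), rep("1H", sum(n_h)))
  val <- c(unlist(lib@carbonShifts, use.names = FALSE),
           unlist(lib@protonShifts, use.names = FALSE))
  # restore record order: all rows of molecule 1 first, carbons then protons
  ord <- order(match(ids, lib@ids), match(nuc, .NUCLEI))
  df <- data.frame(molecule_id = ids[ord], solvent = lib@solvent,
                   nucleus = nuc[ord], shift_ppm = .fullPrec(val[ord]),
                   smiles = ifelse(is.na(smi[ord]), "", smi[ord]))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
}

.writeJsonLibrary <- function(lib, path) {
  mols <- lapply(seq_along(lib@ids), function(i) {
    m <- list(molecule_id = lib@ids[i])
    if (!is.na(lib@smiles[i])) m$smiles <- lib@smiles[i]
    m$carbon_shifts <- lib@carbonShifts[[i]]
    m$proton_shifts <- lib@protonShifts[[i]]
    m
  })
  # digits = I(17): 17 *significant* digits, enough for exact double round-trip
  jsonlite::write_json(list(solvent = lib@solvent, molecules = mols), path,
                       auto_unbox = TRUE, digits = I(17), pretty = FALSE)
}
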