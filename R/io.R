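# Structure file input/output. SDF (V2000, multi-record) is parsed here with
# formal-charge and per-record topology handling; multi-model PDB goes
# through bio3d; concatenated XYZ frames are read directly (no established
# R reader exists for that layout). Bonds are inferred from covalent radii
# for formats that carry no connectivity.

#' Parse a structure file into a molecule and its conformers
#'
#' Multi-record SDF and multi-model PDB files yield one conformer per
#' record/model; all records must share the same topology. XYZ input is a
#' concatenation of frames (`natoms / comment / atom lines`).
#'
#' @param path path to the file (or a character vector of lines via `text`).
#' @param format `"sdf"`, `"pdb"` or `"xyz"`; default guesses from the
#'   file extension.
#' @param text optional character vector of file lines instead of `path`.
#' @param energy_field SDF data field (case-insensitive) read as
#'   per-conformer energy when present.
#' @return list with elements `molecule` ([molecule()]) and `conformers`
#'   (list of [conformer()]).
#' @export
parse_structure <- function(path = NULL, format = NULL, text = NULL,
                            energy_field = "energy") {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      stop(sprintf("input file not found: %s", path %||% "<NULL>"), call. = FALSE)
    if (is.null(format))
      format <- switch(tolower(tools::file_ext(path)),
                       sdf = , sd = , mol = "sdf", pdb = "pdb", xyz = "xyz",
                       stop("cannot guess format from extension; pass format=",
                            call. = FALSE))
  } else if (is.null(format)) {
    stop("format must be given when parsing from text", call. = FALSE)
  }
  format <- match.arg(tolower(format), c("sdf", "pdb", "xyz"))
  if (format == "pdb") {
    if (is.null(path)) {
      path <- tempfile(fileext = ".pdb"); on.exit(unlink(path))
      writeLines(text, path)
    }
    return(parse_pdb_file(path))
  }
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("empty structure input", call. = FALSE)
  switch(format,
         sdf = parse_sdf_lines(lines, energy_field = energy_field),
         xyz = parse_xyz_lines(lines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- SDF (V2000) ----------------------------------------------------------

.sdf_old_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                     `5` = -1L, `6` = -2L, `7` = -3L)

parse_sdf_record <- function(lines, offset) {
  if (length(lines) < 4L)
    stop(sprintf("SDF record starting at line %d is truncated", offset),
         call. = FALSE)
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb))
    stop(sprintf("malformed counts line at line %d: '%s'", offset + 3L, counts),
         call. = FALSE)
  need <- 4L + na + nb
  if (length(lines) < need)
    stop(sprintf(
      "SDF record at line %d declares %d atoms and %d bonds but ends early (atom/bond line missing near line %d)",
      offset, na, nb, offset + length(lines) - 1L), call. = FALSE)
  atom_lines <- lines[5L:(4L + na)]
  xyz <- matrix(NA_real_, na, 3L)
  el <- character(na)
  chg <- integer(na)
  for (k in seq_len(na)) {
    ln <- atom_lines[k]
    if (nchar(ln) < 34L)
      stop(sprintf("malformed atom line at line %d: '%s'", offset + 3L + k, ln),
           call. = FALSE)
    xyz[k, ] <- suppressWarnings(as.numeric(c(substr(ln, 1, 10),
                                              substr(ln, 11, 20),
                                              substr(ln, 21, 30))))
    el[k] <- trimws(substr(ln, 32, 34))
    code <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    if (!is.na(code) && as.character(code) %in% names(.sdf_old_charge))
      chg[k] <- .sdf_old_charge[[as.character(code)]]
  }
  if (anyNA(xyz))
    stop(sprintf("non-numeric coordinate in atom block starting at line %d",
                 offset + 4L), call. = FALSE)
  bonds <- data.frame(i = integer(nb), j = integer(nb), order = integer(nb))
  if (nb > 0) for (k in seq_len(nb)) {
    ln <- lines[4L + na + k]
    bonds$i[k] <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    bonds$j[k] <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    bonds$order[k] <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    if (is.na(bonds$i[k]) || is.na(bonds$j[k]) || is.na(bonds$order[k]))
      stop(sprintf("malformed bond line at line %d: '%s'",
                   offset + 3L + na + k, ln), call. = FALSE)
  }
  rest <- if (length(lines) > need) lines[(need + 1L):length(lines)] else character()
  # properties block: M CHG overrides all old-style charges
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines)) {
    chg[] <- 0L
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      npair <- f[1]
      for (p in seq_len(npair)) {
        chg[f[2 * p]] <- f[2 * p + 1L]
      }
    }
  }
  # data items: "> <name>" then value line(s)
  data <- list()
  hdr <- grep("^>", rest)
  for (h in hdr) {
    nm <- sub(".*<([^>]+)>.*", "\\1", rest[h])
    if (h + 1L <= length(rest)) data[[nm]] <- trimws(rest[h + 1L])
  }
  list(name = trimws(lines[1L]), elements = el, coords = xyz,
       bonds = bonds, charges = chg, data = data)
}

parse_sdf_lines <- function(lines, energy_field = "energy") {
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, ends + 1L)
  if (!length(ends)) { starts <- 1L; ends <- length(lines) + 1L }
  recs <- list()
  for (r in seq_along(ends)) {
    block <- lines[starts[r]:(ends[r] - 1L)]
    if (all(!nzchar(trimws(block)))) next
    recs[[length(recs) + 1L]] <- parse_sdf_record(block, starts[r])
  }
  if (length(starts) > length(ends) && starts[length(starts)] <= length(lines)) {
    block <- lines[starts[length(starts)]:length(lines)]
    if (any(nzchar(trimws(block))))
      recs[[length(recs) + 1L]] <- parse_sdf_record(block, starts[length(starts)])
  }
  if (!length(recs)) stop("no SDF records found", call. = FALSE)
  ref <- recs[[1L]]
  mol <- molecule(ref$elements, ref$bonds, ref$charges,
                  name = if (nzchar(ref$name)) ref$name else NULL)
  confs <- vector("list", length(recs))
  for (r in seq_along(recs)) {
    rc <- recs[[r]]
    if (!identical(normalize_element(rc$elements), mol$elements) ||
        !identical(rc$bonds, ref$bonds))
      stop(sprintf("topology mismatch: SDF record %d differs from record 1", r),
           call. = FALSE)
    en <- NULL
    dn <- tolower(names(rc$data))
    hit <- which(dn == tolower(energy_field))
    if (length(hit)) en <- suppressWarnings(as.numeric(rc$data[[hit[1L]]]))
    confs[[r]] <- conformer(rc$coords, energy = en, id = r)
  }
  list(molecule = mol, conformers = confs)
}

#' Write a molecule and conformers to a V2000 SDF file
#'
#' One record per conformer; per-conformer energies (when present) are
#' written as a `> <energy>` data field so they round-trip through
#' [parse_structure()].
#'
#' @param mol a [molecule()].
#' @param conformers list of [conformer()]s (a single conformer is accepted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mol, conformers, path) {
  if (inherits(conformers, "molcham_conf")) conformers <- list(conformers)
  out <- character()
  for (cf in conformers) {
    if (nrow(cf$coords) != mol$n_atoms)
      stop("conformer does not match molecule atom count", call. = FALSE)
    rec <- c(mol$name %||% "molcham", "  molcham", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     mol$n_atoms, nrow(mol$bonds)))
    rec <- c(rec, vapply(seq_len(mol$n_atoms), function(k)
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              cf$coords[k, 1], cf$coords[k, 2], cf$coords[k, 3],
              mol$elements[k]), ""))
    if (nrow(mol$bonds))
      rec <- c(rec, vapply(seq_len(nrow(mol$bonds)), function(k)
        sprintf("%3d%3d%3d  0", mol$bonds$i[k], mol$bonds$j[k],
                mol$bonds$order[k]), ""))
    charged <- which(mol$charges != 0L)
    if (length(charged)) {
      for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
        rec <- c(rec, paste0("M  CHG", sprintf("%3d", length(grp)),
                             paste0(sprintf("%4d%4d", grp, mol$charges[grp]),
                                    collapse = "")))
      }
    }
    rec <- c(rec, "M  END")
    if (!is.null(cf$energy))
      rec <- c(rec, "> <energy>", format(cf$energy, digits = 12), "")
    rec <- c(rec, "$$$$")
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

# ---- PDB (multi-model) ----------------------------------------------------

parse_pdb_file <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  el <- pdb$atom$elesy
  if (is.null(el) || all(!nzchar(trimws(el)))) {
    # fall back on the leading letters of the atom name
    el <- sub("^[0-9]*", "", trimws(pdb$atom$elety))
    el <- sub("([A-Za-z]+).*", "\\1", el)
    el <- ifelse(nchar(el) > 1 &
                   !(normalize_element(el) %in% .element_table$symbol),
                 substr(el, 1, 1), el)
  }
  el <- normalize_element(trimws(el))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n <- length(el)
  if (ncol(xyz) != 3L * n)
    stop("topology mismatch: PDB models differ in atom count", call. = FALSE)
  first <- matrix(xyz[1L, ], ncol = 3L, byrow = TRUE)
  bonds <- pdb_conect_bonds(path, n)
  if (is.null(bonds)) bonds <- infer_bonds(el, first)
  mol <- molecule(el, bonds, name = basename(path))
  confs <- lapply(seq_len(nrow(xyz)), function(m)
    conformer(matrix(xyz[m, ], ncol = 3L, byrow = TRUE), id = m))
  list(molecule = mol, conformers = confs)
}

pdb_conect_bonds <- function(path, n) {
  ln <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  pairs <- list()
  for (l in ln) {
    f <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7, nchar(l))),
                                              "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) < 2L) next
    for (p in f[-1L]) pairs[[length(pairs) + 1L]] <- sort(c(f[1L], p))
  }
  if (!length(pairs)) return(NULL)
  b <- unique(do.call(rbind, pairs))
  b <- b[b[, 1] >= 1 & b[, 2] <= n, , drop = FALSE]
  data.frame(i = b[, 1], j = b[, 2], order = 1L)
}

# Distance-based bond inference (single bonds only): d <= r_cov(i) +
# r_cov(j) + 0.45 A. Used for PDB without CONECT records and for XYZ.
infer_bonds <- function(elements, coords, slack = 0.45) {
  rc <- element_property(elements, "cov")
  n <- length(elements)
  ii <- integer(); jj <- integer()
  for (a in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(coords[(a + 1L):n, , drop = FALSE]) - coords[a, ])^2))
    hit <- which(d > 0.3 & d <= rc[a] + rc[(a + 1L):n] + slack)
    if (length(hit)) { ii <- c(ii, rep(a, length(hit))); jj <- c(jj, a + hit) }
  }
  data.frame(i = ii, j = jj, order = rep(1L, length(ii)))
}

# ---- XYZ (concatenated frames) -------------------------------------------

parse_xyz_lines <- function(lines) {
  pos <- 1L
  frames <- list(); el_ref <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na < 1L)
      stop(sprintf("malformed XYZ atom-count line at line %d: '%s'",
                   pos, lines[pos]), call. = FALSE)
    if (pos + 1L + na > length(lines))
      stop(sprintf("XYZ frame at line %d declares %d atoms but input ends early",
                   pos, na), call. = FALSE)
    block <- lines[(pos + 2L):(pos + 1L + na)]
    f <- strsplit(trimws(block), "\\s+")
    if (any(lengths(f) < 4L))
      stop(sprintf("malformed XYZ atom line near line %d", pos + 2L),
           call. = FALSE)
    el <- vapply(f, `[[`, "", 1L)
    xyz <- t(vapply(f, function(v) as.numeric(v[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop(sprintf("non-numeric coordinate in XYZ frame at line %d", pos),
           call. = FALSE)
    if (is.null(el_ref)) el_ref <- normalize_element(el)
    else if (!identical(normalize_element(el), el_ref))
      stop("topology mismatch: XYZ frames differ in element sequence",
           call. = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + na
  }
  if (!length(frames)) stop("no XYZ frames found", call. = FALSE)
  bonds <- infer_bonds(el_ref, frames[[1L]])
  mol <- molecule(el_ref, bonds)
  confs <- lapply(seq_along(frames), function(k) conformer(frames[[k]], id = k))
  list(molecule = mol, conformers = confs)
}

# ---- retention tables -----------------------------------------------------

#' Read a chromatographic retention-time table
#'
#' Expects a delimited text file with columns `system`, `pct_acn`, `tr_min`
#' and `t0_min` (header required; comma or tab separated).
#'
#' @param path input file.
#' @return data frame with one row per (system, mobile-phase) measurement.
#' @export
read_retention_table <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("system", "pct_acn", "tr_min", "t0_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("retention table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(df$pct_acn < 0 | df$pct_acn > 100))
    stop("pct_acn must lie in [0, 100]", call. = FALSE)
  if (any(df$t0_min <= 0))
    stop("dead time t0 must be positive", call. = FALSE)
  df
}
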