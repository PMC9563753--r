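#' Monoisotopic masses of the light isotopes used for negative-mode sphingolipid ions
#'
#' Single-isotope table (12C is exactly 12 by definition); `e` is the
#' electron mass, added once per singly charged anion.
#'
#' @format Named numeric vector of masses in Da.
#' @keywords internal
MONOISOTOPIC <- c(
  C = 12,
  H = 1.00782503,
  N = 14.0030740,
  O = 15.9949146,
  P = 30.9737615,
  S = 31.9720707,
  e = 0.00054858
)

#' Lipid classes the shorthand parser understands
#' @keywords internal
LIPID_CLASSES <- c("SM", "SHexCer", "SHex2Cer", "StS")

#' Negative-mode adduct used for each lipid class
#'
#' Sulfatides and sterol sulfates ionize as the deprotonated molecule,
#' sphingomyelins as the demethylated ion.
#' @keywords internal
CLASS_ADDUCT <- c(
  SM = "[M-CH3]-", SHexCer = "[M-H]-", SHex2Cer = "[M-H]-", StS = "[M-H]-"
)

#' Parse a shorthand sphingolipid name
#'
#' Accepts sum-level names of the form `"<CLASS> <C>:<DB>;O<k>"` (e.g.
#' `"SHexCer 42:1;O3"`) and species-level names
#' `"<CLASS> <base>:<DB>;O<k>/<acyl>:<DB>"` (e.g. `"SHexCer 18:1;O2/12:0"`),
#' which are normalized to sum-level totals by adding the chain carbons and
#' double bonds. The `;Ok` descriptor counts hydroxyl-type oxygens of the
#' ceramide beyond the amide carbonyl.
#'
#' @param name Shorthand name, class token first.
#' @return A list with fields `name`, `lipid_class`, `carbons`,
#'   `double_bonds`, `hydroxyl_count` and `sum_name` (the normalized
#'   sum-level shorthand; equals `name` for sum-level input).
#' @examples
#' parse_shorthand("SHexCer 42:1;O3")
#' parse_shorthand("SHexCer 18:1;O2/12:0")$sum_name
#' @export
parse_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  tokens <- strsplit(trimws(name), "[ ]+")[[1]]
  if (length(tokens) != 2L)
    stop("malformed lipid name (expected '<CLASS> <descriptor>'): '", name, "'")
  cls <- tokens[1L]
  if (!cls %in% LIPID_CLASSES)
    stop("unknown lipid class token '", cls, "' in '", name, "'")
  desc <- tokens[2L]

  sum_pat <- "^([0-9]+):([0-9]+);O([0-9]+)$"
  spc_pat <- "^([0-9]+):([0-9]+);O([0-9]+)/([0-9]+):([0-9]+)$"
  if (grepl(spc_pat, desc)) {
    g <- as.integer(regmatches(desc, regexec(spc_pat, desc))[[1]][-1])
    carbons <- g[1] + g[4]
    dbs <- g[2] + g[5]
    oh <- g[3]
  } else if (grepl(sum_pat, desc)) {
    g <- as.integer(regmatches(desc, regexec(sum_pat, desc))[[1]][-1])
    carbons <- g[1]
    dbs <- g[2]
    oh <- g[3]
  } else {
    stop("malformed descriptor '", desc, "' in '", name, "'")
  }
  if (cls %in% c("SM", "SHexCer", "SHex2Cer") && !oh %in% 2:4)
    stop("hydroxyl count ;O", oh, " outside the sphingolipid range 2-4 in '",
         name, "'")
  list(
    name = name,
    lipid_class = cls,
    carbons = carbons,
    double_bonds = dbs,
    hydroxyl_count = oh,
    sum_name = sprintf("%s %d:%d;O%d", cls, carbons, dbs, oh)
  )
}

#' Derive the elemental formula of a sphingolipid from its shorthand descriptor
#'
#' The ceramide core with n carbons, d double bonds and k hydroxyl-type
#' oxygens has composition C_n H_(2n+1-2d) N O_(k+1). Head groups are added
#' as condensation residues: phosphocholine (C5H14NO4P minus H2O) for SM,
#' one or two anhydrohexoses (C6H10O5) plus SO3 for SHexCer/SHex2Cer.
#' Sterol sulfates have no constructive rule and must carry a user-supplied
#' formula or m/z.
#'
#' @param species List as returned by [parse_shorthand()].
#' @return Named integer vector of element counts.
#' @examples
#' derive_formula(parse_shorthand("SHexCer 18:1;O2/12:0"))  # C36 H69 N O11 S
#' @export
derive_formula <- function(species) {
  cls <- species$lipid_class
  if (cls == "StS")
    stop("formula required: StS species carry no constructive formula rule; ",
         "supply 'formula' or 'mz' explicitly for '", species$name, "'")
  n <- species$carbons
  d <- species$double_bonds
  k <- species$hydroxyl_count
  stopifnot(n >= 0, d >= 0, k >= 0)
  core <- c(C = n, H = 2 * n + 1 - 2 * d, N = 1, O = k + 1)
  if (core[["H"]] < 0) stop("negative hydrogen count for '", species$name, "'")
  f <- switch(cls,
    SM       = add_formulas(core, c(C = 5, H = 12, N = 1, O = 3, P = 1)),
    SHexCer  = add_formulas(core, c(C = 6, H = 10, O = 8, S = 1)),
    SHex2Cer = add_formulas(core, c(C = 12, H = 20, O = 13, S = 1))
  )
  f[f != 0]
}

add_formulas <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  for (nm in names(a)) out[nm] <- out[nm] + a[[nm]]
  for (nm in names(b)) out[nm] <- out[nm] + b[[nm]]
  out
}

#' Format an element-count vector as a Hill-order formula string
#' @param counts Named integer vector of element counts.
#' @return Character scalar, e.g. `"C36H69NO11S"`.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

#' Parse a formula string into element counts
#' @param formula Character scalar such as `"C35H71N2O6P"`.
#' @return Named integer vector.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("unparseable formula '", formula, "'")
  out <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + cnt
  }
  out
}

#' Monoisotopic mass of a neutral formula
#' @param counts Named integer vector of element counts.
#' @return Mass in Da.
#' @export
neutral_mass <- function(counts) {
  counts <- counts[counts > 0]
  unknown <- setdiff(names(counts), setdiff(names(MONOISOTOPIC), "e"))
  if (length(unknown))
    stop("no monoisotopic mass for element(s): ", paste(unknown, collapse = ", "))
  sum(MONOISOTOPIC[names(counts)] * counts)
}

#' m/z of a negative-mode adduct ion
#'
#' `[M-H]-` removes one hydrogen, `[M-CH3]-` removes a methyl; one electron
#' mass is added to the anion. At the working resolution (R = 100,000) the
#' electron mass (0.55 mDa) is within the resolved width and is not ignored.
#'
#' @param formula Named element-count vector or formula string of the
#'   neutral molecule.
#' @param adduct `"[M-H]-"` or `"[M-CH3]-"`.
#' @return Ion m/z in Da.
#' @examples
#' ion_mz(derive_formula(parse_shorthand("SHexCer 30:1;O2")), "[M-H]-")
#' @export
ion_mz <- function(formula, adduct) {
  if (is.character(formula)) formula <- parse_formula(formula)
  loss <- switch(adduct,
    "[M-H]-"   = c(H = 1L),
    "[M-CH3]-" = c(C = 1L, H = 3L),
    stop("unsupported adduct '", adduct, "'")
  )
  for (el in names(loss)) {
    have <- if (el %in% names(formula)) formula[[el]] else 0L
    if (have < loss[[el]])
      stop("adduct ", adduct, " removes ", loss[[el]], " ", el,
           " but formula has ", have)
  }
  neutral_mass(formula) - neutral_mass(loss) + MONOISOTOPIC[["e"]]
}

#' Build a sorted lipid annotation database from a panel
#'
#' The panel is either a character vector of shorthand names or a data frame
#' with columns `name` and optionally `adduct`, `formula`, `mz`. Adducts
#' default to the class rule (SM as `[M-CH3]-`, all others as `[M-H]-`).
#' Species with a supplied `mz` (sterol sulfates, isotope-labelled internal
#' standards) are stored verbatim; all others get formula-derived masses.
#'
#' @param panel Character vector of names or data frame as above.
#' @param tolerance_ppm Relative mass window used downstream for peak
#'   assignment (default 5 ppm).
#' @param is_names Names (as given in the panel) of internal-standard
#'   channels; recorded in the `is_channel` column.
#' @return A data frame of class `annotation_db`, strictly sorted by
#'   `ion_mz`, with columns `name`, `sum_name`, `lipid_class`, `carbons`,
#'   `double_bonds`, `hydroxyl_count`, `formula`, `neutral_mass`, `adduct`,
#'   `ion_mz`, `is_channel`, and attribute `tolerance_ppm`.
#' @export
build_database <- function(panel, tolerance_ppm = 5, is_names = character(0)) {
  if (is.character(panel)) panel <- data.frame(name = panel)
  stopifnot(is.data.frame(panel), "name" %in% names(panel))
  if (nrow(panel) == 0L) stop("empty lipid panel")

  rows <- lapply(seq_len(nrow(panel)), function(i) {
    nm <- panel$name[i]
    supplied_mz <- if ("mz" %in% names(panel)) panel$mz[i] else NA_real_
    supplied_formula <- if ("formula" %in% names(panel)) panel$formula[i] else NA_character_
    sp <- tryCatch(parse_shorthand(nm), error = function(e) e)
    if (inherits(sp, "error")) {
      # opaque channel (e.g. "StS 3", labelled IS): class given, m/z verbatim
      if (is.na(supplied_mz) || is.null(panel$class) || is.na(panel$class[i]))
        stop(conditionMessage(sp),
             " (opaque channels need 'class' and 'mz' columns)")
      cls <- panel$class[i]
      adduct <- if ("adduct" %in% names(panel) && !is.na(panel$adduct[i]))
        panel$adduct[i] else CLASS_ADDUCT[[cls]]
      return(data.frame(
        name = nm, sum_name = nm, lipid_class = cls,
        carbons = NA_integer_, double_bonds = NA_integer_,
        hydroxyl_count = NA_integer_, formula = NA_character_,
        neutral_mass = NA_real_, adduct = adduct, ion_mz = supplied_mz,
        stringsAsFactors = FALSE
      ))
    }
    adduct <- if ("adduct" %in% names(panel) && !is.na(panel$adduct[i]))
      panel$adduct[i] else CLASS_ADDUCT[[sp$lipid_class]]
    if (!is.na(supplied_mz)) {
      mz <- supplied_mz
      fstr <- supplied_formula
      nmass <- if (!is.na(supplied_formula)) neutral_mass(parse_formula(supplied_formula)) else NA_real_
    } else {
      f <- if (!is.na(supplied_formula)) parse_formula(supplied_formula)
           else derive_formula(sp)
      fstr <- format_formula(f)
      nmass <- neutral_mass(f)
      mz <- ion_mz(f, adduct)
    }
    data.frame(
      name = nm, sum_name = sp$sum_name, lipid_class = sp$lipid_class,
      carbons = sp$carbons, double_bonds = sp$double_bonds,
      hydroxyl_count = sp$hydroxyl_count, formula = fstr,
      neutral_mass = nmass, adduct = adduct, ion_mz = mz,
      stringsAsFactors = FALSE
    )
  })
  db <- do.call(rbind, rows)

  key <- paste(db$name, db$adduct)
  if (anyDuplicated(key))
    stop("duplicate (name, adduct) in panel: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  db$is_channel <- db$name %in% is_names
  db <- db[order(db$ion_mz), , drop = FALSE]
  rownames(db) <- NULL
  attr(db, "tolerance_ppm") <- tolerance_ppm
  class(db) <- c("annotation_db", "data.frame")
  db
}

#' Write an annotation database as delimited text sorted by m/z
#' @param db An `annotation_db`.
#' @param path Output file path.
#' @export
write_database <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
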