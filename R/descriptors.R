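# QTAIM bond-critical-point bookkeeping, Espinosa bond energies, covalency
# classification, and SAPT component accounting.

#' QTAIM critical-point record
#'
#' @param label bond label, e.g. `"ND-H...OA"`.
#' @param rho electron density at the CP, e a0^-3.
#' @param V_BCP potential energy density at the CP, atomic units.
#' @param laplacian Laplacian of the electron density, e a0^-5.
#' @param H_BCP total energy density at the CP, atomic units.
#' @param cp_type `"BCP"` or `"RCP"`.
#' @param system structure tag, e.g. `"D1"`.
#' @return object of class `critical_point`.
#' @export
critical_point <- function(label, rho, V_BCP, laplacian, H_BCP = NA_real_,
                           cp_type = c("BCP", "RCP"), system = "") {
  cp_type <- match.arg(cp_type)
  if (!is.na(rho) && rho <= 0) stop("rho must be positive at a real critical point")
  structure(list(label = label, cp_type = cp_type, rho = rho, V_BCP = V_BCP,
                 laplacian = laplacian, H_BCP = H_BCP, system = system),
            class = "critical_point")
}

#' Espinosa hydrogen-bond energy from the BCP potential energy density
#'
#' The Espinosa relation estimates a closed-shell bond energy as half the
#' magnitude of the potential energy density at the bond critical point:
#' `E = |V_BCP| / 2`, converted from hartree atomic units with
#' 627.5095 kcal/mol per hartree. It applies to closed-shell contacts
#' (positive Laplacian); for shared-shell (covalent) bonds, where the
#' Laplacian is negative, the relation is not meaningful and `NA` is
#' returned, mirroring the dashes such tables print for covalent rows.
#'
#' @param cp a [critical_point()] of type BCP, or a data.frame of parsed
#'   records (see [read_qtaim_table()]), in which case a vector is returned.
#' @param signed return the signed stabilisation energy `-|V|/2` instead of
#'   the positive magnitude (default FALSE).
#' @return energy in kcal/mol (positive magnitude by default), or `NA` for
#'   shared-shell bonds.
#' @examples
#' cp <- critical_point("OD-H...OA", 0.0384, -0.0381, 0.1349, -0.0022)
#' espinosa_energy(cp)  # ~11.95
#' @export
espinosa_energy <- function(cp, signed = FALSE) {
  if (is.data.frame(cp)) {
    return(vapply(seq_len(nrow(cp)), function(i)
      espinosa_energy(critical_point(cp$label[i], cp$rho[i], cp$V_BCP[i],
                                     cp$laplacian[i], cp$H_BCP[i],
                                     system = if ("system" %in% names(cp)) cp$system[i] else ""),
                      signed = signed),
      numeric(1)))
  }
  stopifnot(inherits(cp, "critical_point"))
  if (cp$cp_type != "BCP") stop("type error: Espinosa energy is defined at BCPs")
  if (is.na(cp$V_BCP) || is.na(cp$laplacian)) stop("data error: missing V_BCP or laplacian")
  if (cp$laplacian < 0) return(NA_real_)
  e <- 0.5 * abs(cp$V_BCP) * HARTREE2KCAL
  if (signed) -e else e
}

#' Classify a critical point by Laplacian and energy density
#'
#' Standard QTAIM reading of the signs at a BCP: negative Laplacian marks a
#' shared-shell (covalent) bond; positive Laplacian with positive energy
#' density a closed-shell, electrostatic contact; positive Laplacian with
#' negative energy density a closed-shell but partially covalent
#' interaction (the regime of strong hydrogen bonds). Magnitudes below
#' 1e-6 a.u. are treated as zero and resolved toward the electrostatic
#' class with a message.
#'
#' @param cp a [critical_point()] with `rho`, `V_BCP`, `laplacian`, `H_BCP`.
#' @return one of `"shared_shell_covalent"`, `"closed_shell_electrostatic"`,
#'   `"closed_shell_partially_covalent"`.
#' @export
classify_interaction <- function(cp) {
  stopifnot(inherits(cp, "critical_point"))
  vals <- c(cp$rho, cp$V_BCP, cp$laplacian, cp$H_BCP)
  if (anyNA(vals)) stop("data error: all four scalars are required")
  zero_tol <- 1e-6
  if (cp$laplacian < 0) return("shared_shell_covalent")
  H <- cp$H_BCP
  if (abs(H) < zero_tol) {
    message("H_BCP within 1e-6 of zero; resolving toward the electrostatic class")
    return("closed_shell_electrostatic")
  }
  if (H > 0) "closed_shell_electrostatic" else "closed_shell_partially_covalent"
}

#' SAPT interaction-energy components
#'
#' @param E_elst,E_exch,E_ind,E_disp electrostatic, exchange, induction and
#'   dispersion components, kcal/mol. Exchange must be nonnegative for a
#'   physically meaningful dimer.
#' @param E_total_reported optional printed total for auditing.
#' @param label level/system label.
#' @return object of class `sapt_components`.
#' @export
sapt_components <- function(E_elst, E_exch, E_ind, E_disp,
                            E_total_reported = NA_real_, label = "") {
  vals <- c(E_elst, E_exch, E_ind, E_disp)
  if (any(!is.finite(vals))) stop("data error: components must be finite")
  if (E_exch < 0) stop("data error: exchange component must be >= 0")
  structure(list(E_elst = E_elst, E_exch = E_exch, E_ind = E_ind,
                 E_disp = E_disp, E_total_reported = E_total_reported,
                 label = label),
            class = "sapt_components")
}

#' Total SAPT interaction energy
#'
#' @param c a [sapt_components()] object.
#' @return `E_elst + E_exch + E_ind + E_disp`, kcal/mol.
#' @export
sapt_total <- function(c) {
  stopifnot(inherits(c, "sapt_components"))
  c$E_elst + c$E_exch + c$E_ind + c$E_disp
}

#' Audit a SAPT row against its reported total
#'
#' Recomputes the component sum, flags a discrepancy with the reported
#' total beyond `tol`, and reports the sign of the steric balance
#' `E_elst + E_exch` (a positive balance means the first-order
#' electrostatics-plus-exchange part of the interaction is net repulsive,
#' so binding rests on induction and dispersion).
#'
#' @param c a [sapt_components()] with `E_total_reported` set.
#' @param tol tolerance on `|sum - reported|`, kcal/mol.
#' @return list with `sum`, `reported`, `discrepancy`, `pass`,
#'   `steric_balance` and `steric_repulsive`.
#' @export
audit_sapt <- function(c, tol = 0.01) {
  stopifnot(inherits(c, "sapt_components"))
  if (is.na(c$E_total_reported)) stop("data error: no reported total to audit")
  s <- sapt_total(c)
  d <- s - c$E_total_reported
  bal <- c$E_elst + c$E_exch
  list(label = c$label, sum = s, reported = c$E_total_reported,
       discrepancy = d, pass = abs(d) <= tol,
       steric_balance = bal, steric_repulsive = bal > 0)
}

normalize_unicode <- function(x) {
  x <- gsub("−", "-", x)     # Unicode minus
  x <- gsub("…", "...", x)   # ellipsis
  x
}

#' Read tabulated QTAIM or SAPT descriptors
#'
#' Delimited text (comma or whitespace) with a header naming the fields.
#' Unicode minus signs and ellipses are normalised before parsing. A QTAIM
#' table must carry `label, rho, V_BCP, laplacian, H_BCP` (an `E1` column,
#' with `-` for covalent rows, and a `system` column are optional); a SAPT
#' table `label, E_elst, E_exch, E_ind, E_disp` (optional `E_total`).
#' [read_descriptor_tables()] dispatches on the header.
#'
#' @param path file path.
#' @return data.frame of typed records; SAPT rows can be turned into
#'   [sapt_components()] with [as_sapt_components()].
#' @export
read_qtaim_table <- function(path) {
  df <- read_clean_table(path)
  need <- c("label", "rho", "V_BCP", "laplacian", "H_BCP")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("rho", "V_BCP", "laplacian", "H_BCP"))
    df[[col]] <- parse_numeric(df[[col]], col)
  if ("E1" %in% names(df)) {
    df$E1 <- suppressWarnings(as.numeric(ifelse(df$E1 %in% c("-", "--", ""),
                                                NA, df$E1)))
  }
  df
}

#' @rdname read_qtaim_table
#' @export
read_sapt_table <- function(path) {
  df <- read_clean_table(path)
  need <- c("label", "E_elst", "E_exch", "E_ind", "E_disp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(c("E_elst", "E_exch", "E_ind", "E_disp", "E_total"),
                        names(df)))
    df[[col]] <- parse_numeric(df[[col]], col)
  df
}

#' @rdname read_qtaim_table
#' @export
read_descriptor_tables <- function(path) {
  header <- normalize_unicode(readLines(path, n = 1))
  if (grepl("V_BCP", header)) read_qtaim_table(path)
  else if (grepl("E_elst", header)) read_sapt_table(path)
  else stop("format error: header names neither QTAIM nor SAPT fields")
}

#' Turn parsed SAPT rows into component objects
#'
#' @param df data.frame from [read_sapt_table()].
#' @return list of [sapt_components()].
#' @export
as_sapt_components <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    sapt_components(df$E_elst[i], df$E_exch[i], df$E_ind[i], df$E_disp[i],
                    E_total_reported = if ("E_total" %in% names(df))
                      df$E_total[i] else NA_real_,
                    label = df$label[i]))
}

read_clean_table <- function(path) {
  lines <- normalize_unicode(readLines(path))
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty table")
  sep <- if (grepl(",", lines[1])) "," else ""
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "#")
  names(df) <- trimws(names(df))
  df
}

parse_numeric <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & !(x %in% c("NA", "")))
  if (length(bad))
    stop(sprintf("format error: non-numeric value '%s' in column %s, row %d",
                 x[bad[1]], col, bad[1]))
  out
}
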