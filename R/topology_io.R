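#' Write a topology to a plain-text file
#'
#' Documented text format mirroring GROMACS .top sections: `[ atoms ]`,
#' `[ bonds ]`, `[ angles ]`, `[ impropers ]`, `[ planars ]`, `[ propers ]`,
#' `[ contacts ]` plus a `[ params ]` section for the dual-basin Gaussian
#' and excluded-volume parameters. Values are written with full precision
#' so that a written topology re-reads record-for-record identical.
#'
#' @param topology an [sbm_topology].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  wl <- function(...) writeLines(paste(...), con)
  wl("; sbmfret dual-basin topology")
  wl("[ params ]")
  for (p in c("gauss_A", "gauss_sigma", "eps_nc", "sigma_nc"))
    wl(p, fmt(topology[[p]]))
  wl("[ atoms ]")
  for (i in seq_along(topology$masses))
    wl(i, fmt(topology$masses[i]))
  sec <- function(name, df) {
    wl(paste0("[ ", name, " ]"))
    if (nrow(df))
      writeLines(apply(df, 1, function(r)
        paste(vapply(r, function(v)
          if (is.na(suppressWarnings(as.numeric(v)))) as.character(v)
          else fmt(as.numeric(v)), character(1)), collapse = " ")), con)
  }
  sec("bonds", topology$bonds)
  sec("angles", topology$angles)
  sec("impropers", topology$impropers)
  sec("planars", topology$planars)
  sec("propers", topology$propers)
  wl("[ contacts ]")
  if (nrow(topology$contacts)) {
    cc <- topology$contacts
    writeLines(paste(cc$i, cc$j,
                     ifelse(is.na(cc$r_alpha), "NA", fmt(cc$r_alpha)),
                     ifelse(is.na(cc$r_beta), "NA", fmt(cc$r_beta)),
                     fmt(cc$weight), cc$category), con)
  }
  invisible(path)
}

#' Read a topology written by [write_topology]
#'
#' @param path file path.
#' @return An [sbm_topology].
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^;", lines) & nzchar(trimws(lines))]
  sec_at <- grep("^\\[", lines)
  sec_names <- gsub("[][ ]", "", lines[sec_at])
  get_sec <- function(name) {
    k <- which(sec_names == name)
    if (!length(k)) return(character())
    from <- sec_at[k] + 1
    to <- if (k < length(sec_at)) sec_at[k + 1] - 1 else length(lines)
    if (from > to) character() else lines[from:to]
  }
  parse_num <- function(txt, cols) {
    if (!length(txt)) {
      df <- as.data.frame(setNames(rep(list(numeric()), length(cols)), cols))
      return(df)
    }
    m <- do.call(rbind, strsplit(trimws(txt), "\\s+"))
    df <- as.data.frame(matrix(as.numeric(m), nrow = nrow(m)))
    names(df) <- cols
    df
  }
  pars <- strsplit(trimws(get_sec("params")), "\\s+")
  pars <- setNames(as.numeric(vapply(pars, `[`, "", 2)),
                   vapply(pars, `[`, "", 1))
  atoms <- parse_num(get_sec("atoms"), c("idx", "mass"))
  ct_txt <- get_sec("contacts")
  contacts <- if (length(ct_txt)) {
    m <- do.call(rbind, strsplit(trimws(ct_txt), "\\s+"))
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
               r_alpha = suppressWarnings(as.numeric(m[, 3])),
               r_beta = suppressWarnings(as.numeric(m[, 4])),
               weight = as.numeric(m[, 5]), category = m[, 6],
               stringsAsFactors = FALSE)
  } else empty_contacts()
  fix_int <- function(df, cols) {
    for (cl in cols) df[[cl]] <- as.integer(df[[cl]])
    df
  }
  sbm_topology(
    masses = atoms$mass,
    bonds = fix_int(parse_num(get_sec("bonds"),
                              c("i", "j", "r0", "eps")), c("i", "j")),
    angles = fix_int(parse_num(get_sec("angles"),
                               c("i", "j", "k", "theta0", "eps")),
                     c("i", "j", "k")),
    impropers = fix_int(parse_num(get_sec("impropers"),
                                  c("i", "j", "k", "l", "chi0", "eps")),
                        c("i", "j", "k", "l")),
    planars = fix_int(parse_num(get_sec("planars"),
                                c("i", "j", "k", "l", "chi0", "eps")),
                      c("i", "j", "k", "l")),
    propers = fix_int(parse_num(get_sec("propers"),
                                c("i", "j", "k", "l", "phi0", "eps")),
                      c("i", "j", "k", "l")),
    contacts = contacts,
    gauss_A = pars[["gauss_A"]], gauss_sigma = pars[["gauss_sigma"]],
    eps_nc = pars[["eps_nc"]], sigma_nc = pars[["sigma_nc"]])
}
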