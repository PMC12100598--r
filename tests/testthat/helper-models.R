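# shared fixtures, built in code once per suite run and memoized

tq <- default_q_grid(0.05, 3, 80)

.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# coarse synthetic dimer (fast; ~100 beads) and its scattering curve
fx_dimer <- function() {
  fixture("dimer", function() make_synthetic_dimer(bead_spacing = 1.0))
}
fx_curve_dimer <- function() {
  fixture("c_dimer", function() debye_intensity(fx_dimer(), tq))
}

# reference helical tubule (r = 12 nm, p = 12 nm, h = 60 nm) and its curve
fx_tubule <- function() {
  fixture("tubule", function() build_inverted_helical_tubule(12, 12, 60, 8))
}
fx_curve_tubule <- function() {
  fixture("c_tubule", function() {
    assembly_intensity(fx_tubule(), fx_dimer(), tq, exact_limit = 2000)
  })
}

# a tiny 4-atom PDB fixture written in code (fixed-column PDB format)
write_toy_pdb <- function(path) {
  fmt <- "%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, "ATOM", 1L, " N", "ALA", "A", 1L, 0, 0, 0, 1, 0, "N"),
    sprintf(fmt, "ATOM", 2L, " CA", "ALA", "A", 1L, 1.5, 0, 0, 1, 0, "C"),
    sprintf(fmt, "ATOM", 3L, " O", "ALA", "A", 1L, 0, 2, 0, 1, 0, "O"),
    sprintf(fmt, "HETATM", 4L, "MG", "MG", "A", 2L, 0, 0, 3, 1, 0, "MG"),
    "END"
  )
  writeLines(lines, path)
  path
}

# three-component library (free dimer, short tubule, hexagonal bundle of
# long tubules) shared by the mixture-fit tests
fx_library <- function() {
  fixture("mix_lib", function() {
    dm <- fx_dimer()
    short <- build_inverted_helical_tubule(12, 12, 10, 8)
    long <- build_inverted_helical_tubule(12, 12, 100, 8)
    bun <- build_bundle(long, a = 30, mode = "hexagonal")
    list(lib = component_library(
      dimer = list(curve = fx_curve_dimer(), n_dimers = 1),
      short_tubule = list(curve = assembly_intensity(short, dm, tq,
                                                     exact_limit = 2000),
                          n_dimers = n_subunits(short)),
      bundle = list(curve = assembly_intensity(bun, dm, tq,
                                               exact_limit = 2000),
                    n_dimers = n_subunits(bun))),
      n = c(1, n_subunits(short), n_subunits(bun)))
  })
}
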