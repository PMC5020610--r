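# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

helix12 <- function() fx("helix12", build_backbone(rep("ALA", 12), -57, -47))

hairpin20 <- function() fx("hairpin20",
  build_hairpin(rep("ALA", 20), 1:8, 9:12, 13:20))

hiapp_hairpin <- function() fx("hiapp_hairpin",
  build_hairpin(hiapp_sequence(), 8:16, 17:24, 25:33))

sheet_dimer37 <- function() fx("sheet_dimer37",
  build_sheet_dimer(hiapp_sequence(), 8:16, 17:24, 25:33))

# A small homodimer mixture ensemble (chain-independent RMSD fixtures)
dimer_mix <- function() fx("dimer_mix", {
  sq <- rep("ALA", 10)
  generate_mixture(list(
    h = mixture_component("helix_dimer", 0.5, sequence = sq),
    s = mixture_component("strand_dimer", 0.5, sequence = sq)),
    n_frames = 12, seed = 42, jitter = 0.01)
})

# Tiny two-chain topology with one "CA" bead per residue, for contact tests
bead_dimer_topology <- function(n_res = 3) {
  topology(data.frame(
    chain = rep(c("A", "B"), each = n_res),
    resid = rep(seq_len(n_res), 2),
    resname = "GLY", name = "CA", element = "C", class = "main_chain"))
}

# One-atom "ligand" conformation helpers for CCS tests
point_atoms <- function(xyz, element = "C") {
  xyz <- matrix(xyz, ncol = 3)
  top <- topology(data.frame(
    chain = "L", resid = 1, resname = "XXX",
    name = paste0("X", seq_len(nrow(xyz))), element = element,
    class = "ligand"))
  conformation(top, xyz)
}

random_rotation_seeded <- function(seed) {
  withr::with_seed(seed, dimerscope:::random_rotation())
}

expect_partition_equal <- function(a, b) {
  norm <- function(cl) {
    m <- lapply(cl, function(x) sort(x$members))
    m[order(vapply(m, min, numeric(1)))]
  }
  expect_identical(norm(a), norm(b))
}

# Ligand placement with azimuth-seed retries (some azimuths clash with the
# peptide surface; geometry is unaffected by the retry).
place_with_retry <- function(conf, ring, d, ang, seed) {
  for (k in 0:39) {
    out <- tryCatch(
      place_ligand_ring(conf, ring, d, ang, seed = seed + k,
                        side = if (k %% 2 == 0) 1 else -1),
      error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("no clash-free placement found")
}
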