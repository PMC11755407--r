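# Shared fixtures, computed lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small planted-rule molecular dataset (noise-free for exact oracles)
fx_dataset_clean <- function() fixture("ds_clean", function() {
  generate_dataset(synthetic_spec(n_total = 400, active_fraction = 0.05,
                                  label_noise = 0, seed = 7))
})

# matching circular fingerprints
fx_fps_clean <- function() fixture("fps_clean", function() {
  ds <- fx_dataset_clean()
  fp_morgan(ds$records$smiles, ids = ds$records$id)
})

# binary matrix with a planted 3-bit rule: b1 & (b2 | b3), ~26% positives
fx_matrix_rule <- function() fixture("mat_rule", function() {
  set.seed(42)
  n <- 600
  x <- matrix(rbinom(n * 96, 1, 0.4), n, 96,
              dimnames = list(sprintf("m%03d", seq_len(n)),
                              sprintf("BIT_%03d", seq_len(96))))
  y <- ifelse(x[, 1] == 1 & (x[, 2] == 1 | x[, 3] == 1), "active", "inactive")
  list(x = x, y = y, informative = c("BIT_001", "BIT_002", "BIT_003"))
})

# larger/lower-noise variant for the network trainer (more rows per noise
# dimension so a memorizing net still generalizes)
fx_matrix_mlp <- function() fixture("mat_mlp", function() {
  set.seed(42)
  n <- 900
  x <- matrix(rbinom(n * 48, 1, 0.4), n, 48,
              dimnames = list(sprintf("m%03d", seq_len(n)),
                              sprintf("BIT_%03d", seq_len(48))))
  y <- ifelse(x[, 1] == 1 & (x[, 2] == 1 | x[, 3] == 1), "active", "inactive")
  list(x = x, y = y, train = 1:700, test = 701:900)
})

# pair of embedded conformers reused by 3D/voxel/pose tests
fx_conformers <- function() fixture("confs", function() {
  embed_conformers(c(paracetamol = "CC(=O)Nc1ccc(O)cc1",
                     ethanol = "CCO",
                     biphenylamide = "O=C(NC)c1ccc(-c2ccccc2)cc1"))
})

write_temp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}
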