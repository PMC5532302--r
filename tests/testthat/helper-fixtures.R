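# Shared builders for small in-code fixtures.

# omics_matrix from a plain matrix, labelling the first n_tumor columns tumor
make_omics <- function(values, layer, n_tumor) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  grp <- setNames(rep(c("tumor", "normal"),
                      c(n_tumor, ncol(values) - n_tumor)), colnames(values))
  omics_matrix(values, layer, grp)
}

# two-group matrix with per-row tumor/normal means
make_two_group <- function(tumor_means, normal_means, n_tumor = 5L,
                           n_normal = 5L, sd = 0, layer = "expression",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- length(tumor_means)
  vals <- cbind(
    matrix(rnorm(g * n_tumor, tumor_means, sd), g),
    matrix(rnorm(g * n_normal, normal_means, sd), g))
  make_omics(vals, layer, n_tumor)
}

# temp TSV matrix file with sidecar-style group vector
write_matrix_file <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# membership list + passenger set reconstructed from the packaged
# association table (module sizes and passenger counts are table columns)
table2_membership <- function() {
  t2 <- table2_fixture()
  mods <- t2[!duplicated(t2$module), ]
  members <- lapply(seq_len(nrow(mods)), function(i)
    sprintf("m%s_g%03d", mods$module[i], seq_len(mods$n_genes[i])))
  names(members) <- as.character(mods$module)
  passengers <- unlist(lapply(seq_len(nrow(mods)), function(i)
    sprintf("m%s_g%03d", mods$module[i], seq_len(mods$n_passengers[i]))))
  list(members = members, passengers = passengers)
}
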