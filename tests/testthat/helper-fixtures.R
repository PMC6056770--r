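# Fixture builders shared across tests. Everything is generated in code;
# nothing binary is checked in.

# tiny abundance matrix: 2 conditions x 2 replicates
toy_matrix <- function(values = NULL, n_prot = 3L) {
  if (is.null(values)) {
    values <- matrix(seq_len(n_prot * 4L), n_prot, 4L)
  }
  rownames(values) <- sprintf("P%d", seq_len(nrow(values)))
  colnames(values) <- c("A_r1", "A_r2", "B_r1", "B_r2")
  abundance_matrix(values, data.frame(
    sample = colnames(values),
    condition = rep(c("A", "B"), each = 2L),
    replicate = rep(1:2, 2L)))
}

write_toy_tables <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mat <- file.path(dir, "abundance.tsv")
  des <- file.path(dir, "design.tsv")
  writeLines(c(
    "protein\tA_r1\tA_r2\tB_r1\tB_r2",
    "P1\t1\t2\t3\t4",
    "P2\t5\t6\t7\t8",
    "P3\t9\t10\t11\t12"), mat)
  writeLines(c(
    "sample\tcondition\treplicate",
    "A_r1\tA\t1", "A_r2\tA\t2", "B_r1\tB\t1", "B_r2\tB\t2"), des)
  list(matrix = mat, design = des, dir = dir)
}

# minimal cellular_component ontology:
#   root GO:0005575 (cellular_component)
#     GO:0005739 mitochondrion
#       GO:0005743 inner membrane (is_a)
#         GO:0030964 respiratory complex (part_of inner membrane, is_a
#                     GO:0032991 complex -> diamond via two paths)
#     GO:0005634 nucleus
#     GO:0032991 protein-containing complex (separate branch)
#   GO:0000001 obsolete term
toy_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0005575", "name: cellular_component",
    "namespace: cellular_component", "",
    "[Term]", "id: GO:0005739", "name: mitochondrion",
    "namespace: cellular_component", "is_a: GO:0005575 ! cellular_component", "",
    "[Term]", "id: GO:0005743", "name: mitochondrial inner membrane",
    "namespace: cellular_component", "is_a: GO:0005739 ! mitochondrion", "",
    "[Term]", "id: GO:0032991", "name: protein-containing complex",
    "namespace: cellular_component", "is_a: GO:0005575 ! cellular_component", "",
    "[Term]", "id: GO:0030964", "name: respiratory chain complex",
    "namespace: cellular_component",
    "is_a: GO:0032991 ! protein-containing complex",
    "relationship: part_of GO:0005743 ! mitochondrial inner membrane", "",
    "[Term]", "id: GO:0005634", "name: nucleus",
    "namespace: cellular_component", "is_a: GO:0005575 ! cellular_component", "",
    "[Term]", "id: GO:0000001", "name: gone",
    "namespace: cellular_component", "is_obsolete: true",
    "is_a: GO:0005575 ! cellular_component", ""), path)
  path
}

toy_gaf <- function(path = tempfile(fileext = ".gaf")) {
  row <- function(id, go, qual = "located_in", ev = "IDA")
    paste("UniProtKB", id, "GENE", qual, go, "GO_REF:0000001", ev,
          "", "C", "", "", "protein", "taxon:9606", "20240101", "UP",
          sep = "\t")
  writeLines(c(
    "!gaf-version: 2.2",
    row("P10001", "GO:0030964"),          # via offspring -> mitochondrion
    row("P10002", "GO:0005634"),          # nucleus
    row("P10003", "GO:0005739"),
    row("P10003", "GO:0005634"),          # dual localization
    row("P10004", "GO:0005634", qual = "NOT|located_in"),  # skipped
    row("P10005", "GO:0008150")           # not a CC compartment term
  ), path)
  path
}

# straight-line compartment data: y = intercept + slope * x + residuals
line_points <- function(n, slope = 1, intercept = 0, res_sd = 0.3,
                        x_mean = 25, x_sd = 2) {
  x <- rnorm(n, x_mean, x_sd)
  y <- intercept + slope * x + rnorm(n, 0, res_sd)
  list(x = x, y = y, ids = sprintf("P%05d", seq_len(n)))
}

# condition_means object straight from x/y vectors
means_from_xy <- function(x, y, ids, conditions = c("A", "B")) {
  m <- cbind(x, y)
  dimnames(m) <- list(ids, conditions)
  structure(list(means = m,
                 n_observed = matrix(1L, length(ids), 2L, dimnames = dimnames(m)),
                 is_ratio = FALSE),
            class = "condition_means")
}

annotation_one <- function(ids, compartment = "mitochondrion") {
  as_compartment_annotation(setNames(as.list(rep(compartment, length(ids))), ids))
}

# independent Mann-Whitney oracle: full enumeration of the permutation
# distribution of U for sample sizes n, m (no ties assumed)
enumerate_mw <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
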