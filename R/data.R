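#' Bundled Port Phillip Bay site summaries
#'
#' Published site-level summaries for the seagrass *Heterozostera
#' nigricaulis* at 16 sites in Port Phillip Bay, south-eastern Australia:
#' reproductive investment (seed and spathe densities, per m^2),
#' clonality (N samples, unique multilocus genotypes, genotypic richness
#' R), genetic diversity (Na, He, Ho) and connectivity (network degree,
#' betweenness centrality, relative propagule inflow).  Seed and spathe
#' data are absent at Point Lonsdale.  `port_phillip_fst()` and
#' `port_phillip_flow()` return the companion pairwise F_ST and pairwise
#' flow matrices over the same sites.
#'
#' @return `port_phillip_sites()`: a 16-row tibble; the matrix accessors:
#'   labelled symmetric 16 x 16 matrices.
#' @examples
#' sites <- port_phillip_sites()
#' mean(sites$r)
#' @export
port_phillip_sites <- function() {
  readr::read_csv(
    system.file("extdata", "port_phillip_sites.csv", package = "clonescape"),
    show_col_types = FALSE)
}

#' @rdname port_phillip_sites
#' @export
port_phillip_fst <- function() {
  read_matrix_csv(system.file("extdata", "port_phillip_pairwise_fst.csv",
                              package = "clonescape"))
}

#' @rdname port_phillip_sites
#' @export
port_phillip_flow <- function() {
  read_matrix_csv(system.file("extdata", "port_phillip_pairwise_flow.csv",
                              package = "clonescape"))
}
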