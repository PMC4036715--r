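# Coerce any Matrix (or base matrix) to general double CsparseMatrix.
as_dgc <- function(x) {
  methods::as(methods::as(methods::as(Matrix::Matrix(x), "CsparseMatrix"),
                          "generalMatrix"), "dMatrix")
}
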