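# U6atac snRNA gene model (GRCh38). The genomic span is the annotated
# RNU6ATAC gene; n.1 anchors at the annotated gene boundary (minus strand,
# so n.1 = genomic end). Region and register boundaries are editable
# configuration seeded from U4atac/U6atac secondary-structure models;
# the labels follow the nomenclature used for published RNU6ATAC variant
# annotations. Validated anchor points: n.28 (stem I), n.30 (stem I/II
# boundary), n.36 and n.43 (stem II), n.64 (central stem-loop), and the
# duplex pairing n.43 <-> U4atac n.8.
name: RNU6ATAC
chrom: chr9
start: 134164439
end: 134164564
strand: "-"
regions:
  - label: "U6atac/U4atac stem I pairing region"
    n_start: 17
    n_end: 29
  - label: "stem I/II boundary of the U4atac/U6atac bimolecule"
    n_start: 30
    n_end: 32
  - label: "U6atac/U4atac stem II pairing region"
    n_start: 33
    n_end: 48
  - label: "central stem-loop region"
    n_start: 49
    n_end: 90
registers:
  - partner: RNU4ATAC
    own_start: 17
    own_end: 29
    partner_start: 55
    partner_end: 67
    orientation: antiparallel
  - partner: RNU4ATAC
    own_start: 38
    own_end: 48
    partner_start: 3
    partner_end: 13
    orientation: antiparallel
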