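ddi-lite 0.1 — fixed element subset emitted by export_ddi_lite()

codeBook                      root; attribute version="ddi-lite-0.1"
  stdyDscr
    citation
      titl                    dataset name
    abstract                  dataset description (omitted when empty)
  dataDscr
    var                       one per variable, in dataset order
      @name                   variable name
      labl                    variable label
      qstn                    question text (omitted when absent)
      units                   measurement unit (omitted when absent)
      varFormat               empty element
        @type                 integer | decimal | text | boolean | date
      catgry                  one per category, in category order
        @missing              "Y" | "N"
        catValu               category code
        labl                  category label

The element names are a deliberate small subset of the DDI Codebook
vocabulary; full DDI conformance (versioned namespaces, study-level
citation metadata, nCube/recGrp structures) is out of scope.
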