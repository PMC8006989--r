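# Provenance of the bundled amino-acid property tables

## property_factors.tsv (ten property factors, 20 x 10)

The ten orthogonal physical property factors per amino acid derived by
Kidera, Konishi, Oka, Ooi & Scheraga (1985) "Statistical analysis of the
physical properties of the 20 naturally occurring amino acids",
J. Protein Chem. 4:23-55, from 188 measured physical properties, and used
unchanged by Rackovsky (2009, PNAS 106:14345-14348; Table V) to define
sequence-averaged property-factor encodings of protein sequences. Values
are dimensionless factor scores (each factor approximately standardized
over the 20 amino acids). Factor order f1..f10 follows the original
publication: f1 helix/bend preference, f2 side-chain size, f3 extended
structure preference, f4 hydrophobicity, f5 double-bend preference,
f6 partial specific volume (amino acid composition), f7 flat extended
preference, f8 occurrence in alpha region, f9 pK-C (polarity/ionization),
f10 surrounding hydrophobicity in beta-structure.

## pseaac_properties.tsv (PseAAC correlation triplet, 20 x 3)

The hydrophobicity, hydrophilicity and side-chain-mass values used by
Chou (2001) "Prediction of protein cellular attributes using
pseudo-amino acid composition", Proteins 43:246-255, to build the
sequence-order correlation function of type-1 PseAAC:

- hydrophobicity: Tanford-derived scale as tabulated by Chou (2001);
- hydrophilicity: Hopp & Woods (1981, PNAS 78:3824-3828);
- side_chain_mass: side-chain molecular mass in daltons (glycine = 1).

Raw (unstandardized) values are stored; `load_property_table()`
standardizes each column to mean 0 and sample SD 1 over the 20 amino
acids before the correlation function is evaluated, which is the
standardization convention of type-1 PseAAC.

Both tables are plain TSV with one-letter amino-acid row labels and can be
replaced by user-supplied files of the same shape via
`load_property_table(path)`.
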