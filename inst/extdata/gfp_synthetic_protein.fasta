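>gfp_synthetic 239-aa synthetic stand-in for a GFP-scale protein (not a database accession)
MHFHWYGQVDRSGFATASLQAKVNVWIRPCFEKVKWTAQGLWYQATRDYDRAVLLCFFFK
KTWCREEPQHRLHNIYIFPHHYCQTPGFFTWCFRSCEHDKDAPRSQSNKHTHRECKQQRL
VCNAHAYHRYWTSLNVIQQFGVQLESTRPCNNEAHHQWHNVGKSLTHWIYNGGEPGFVPY
THQVQGAGIAKHTTWFVANWDFCSSICHPLRLVQVECGQHHAHNRPERWKFVTTDFLWP
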