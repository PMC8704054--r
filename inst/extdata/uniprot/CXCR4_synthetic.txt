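ID   CXCR4SYN_SYNTH              Reviewed;         341 AA.
AC   CXCR4SYN;
CC   -!- SYNTHETIC ENTRY generated by qtykit::synth_uniprot_flat; not a real UniProt record.
FT   TRANSMEM        26..48
FT   TRANSMEM        61..84
FT   TRANSMEM        102..122
FT   TRANSMEM        145..169
FT   TRANSMEM        187..206
FT   TRANSMEM        225..244
FT   TRANSMEM        263..283
SQ   SEQUENCE   341 AA;  0 MW;  0000000000000000 CRC64;
     SDGPREPDQN RGSRPEKGGH RSSREVAIAA ILGGAFGFIL FLGGGVAVQN DSPETTERKT
     AAAGAVAGLA LAGLVLAAAG VAAFSTEEQD ESQNQSRGRN PAGLIGGLLV GIFAVILLFI
     LINTDSGNPH PPQDHGGKDT QHSDGAILVV IIGAVVIVAG AVAAAALAVQ EGHEEHPGTS
     PDDSKPAGAG AFIAILGALA ALLAALDDRD DDEQKSDKSQ TNPNGAIVGG GAVLAALGAG
     IFGATPTTRN TPSHSEGTDD HELLGIGGAV GAAFGIIGLA AVGGHKSRPT GTHDHSSTGP
     QENNSKPGGS EKEHHRQSQT RSRHPDHDRT TNSENPTEKD R
//
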