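# Default peptide-family motif library.
# pattern notation: X = any residue, [AB] = single-position alternatives;
# a trailing "amide" in a pattern is informational only - amidation is
# matched through the requires_amide flag, not the sequence.
# anchor: C-terminal | N-terminal | anywhere | exact.
# Exact rows are single-sequence families identified by identity.
family	pattern	anchor	requires_amide	min_len	max_len	note
AST-A	YXFGLamide	C-terminal	yes			FGLamide allatostatins
AST-B	XWXXXXGXWamide	C-terminal	yes			W(X6)Wamide allatostatins
AST-B	XWXXXXGXWGamide	C-terminal	yes			trailing-G variant seen in some isoforms
AST-C	CXFNXXSCF	anywhere	no			C-type allatostatins; two printed isoforms end at the final F
CCHamide	XCXX[WYF]GXXCXGXHamide	C-terminal	yes
CHH	AIAXX	C-terminal	no			conserved caridean type-I CHH C-terminus
DH31	XXDXGLXRGXSGXXXAKXXXXXXXANXXXGPamide	C-terminal	yes
EFLamide	GSEFLamide	C-terminal	yes
FLRFamide	NF[LI]RFamide	C-terminal	yes
Hyrg	RFHYRGF	anywhere	no
kinin	XFX[AP]WAamide	C-terminal	yes
natalisin	WXXRamide	C-terminal	yes
NPF	RPRFamide	C-terminal	yes
orcokinin	NFDEIDRX	N-terminal	no
pyrokinin	PRLamide	C-terminal	yes
RYamide	RYamide	C-terminal	yes
sNPF	PXXRLR[FY]amide	C-terminal	yes
sulfakinin	YGH[ML]RFamide	C-terminal	yes			the Y preceding GH[ML]RF is sulfated
ACP	QITFSRSWVPQ	exact	yes			adipokinetic hormone-corazonin-like peptide
agatoxin-like	WRSCIPRGGSCTHRPKSCCNSSSCRCNLWGTNCRCQRMGLFQQL	exact	yes
calcitonin	TCYINAGLSHGCDYKDLVGAMAEKNYWDSLNSP	exact	yes
CCAP	PFCNAFTGC	exact	yes			crustacean cardioactive peptide
DH44	NSGLSLSIDASMKVLREALYLEMARKKQRQQMLRARHNQALLTTI	exact	yes
EH	ASITSMCIRNCGQCKEMYGDYFHGQACAESCIMTQGVSIPDCNNPATFNRFL	exact	no			eclosion hormone
ETH	DAGHFFAETPKHLPRI	exact	yes			ecdysis triggering hormone
myosuppressin	QDLDHVFLRF	exact	yes
orcokinin	FDSFTTGFGHS	exact	no			orcomyotropin-type isoform
PDH	NSELINSLLGLPKVMNDA	exact	yes			pigment-dispersing hormone
PDH	NSGMINSLLGIPKVMTDA	exact	yes
proctolin	RYLPT	exact	no
RPCH	QLNFSPGW	exact	yes			red pigment-concentrating hormone
SIFamide	GYRKPPFNGSIF	exact	yes
tachykinin	APSGFLGMR	exact	yes
vasopressin	CFITNCPPG	exact	yes
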