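# Published decapod mature peptides in conventional rendering, with their
# reported family. Rows with an empty family are partial/unnamed peptides
# kept for residue- and cysteine-count checks only.
id	rendered	family
ACP	pQITFSRSWVPQamide	ACP
agatoxin_like	WRSCIPRGGSCTHRPKSCCNSSSCRCNLWGTNCRCQRMGLFQQLamide	agatoxin-like
AST_A	SPGYAFGLamide	AST-A
AST_B	ADWSSMRGTWGamide	AST-B
AST_C	pQIRYHQCYFNPISCF	AST-C
AST_CC	GNNNDGRLYWRCYFNAVSCF	AST-C
AST_CCC	SYWKQCAFNAVSCFamide	AST-C
calcitonin	TCYINAGLSHGCDYKDLVGAMAEKNYWDSLNSPamide	calcitonin
CCHamide	VPKGGCLNYGHSCLGAHamide	CCHamide
DH31	GLDLGLGRGFSGSQAAKHLMGLAAANFAGGPamide	DH31
DH44	NSGLSLSIDASMKVLREALYLEMARKKQRQQMLRARHNQALLTTIamide	DH44
CCAP	PFCNAFTGCamide	CCAP
ETH	DAGHFFAETPKHLPRIamide	ETH
EH	ASITSMCIRNCGQCKEMYGDYFHGQACAESCIMTQGVSIPDCNNPATFNRFL	EH
EFLamide_1	IGSEFLamide	EFLamide
EFLamide_2	AMGSEFLamide	EFLamide
FLRFamide_1	GYVDRNFLRFamide	FLRFamide
FLRFamide_2	AAHKNFIRFamide	FLRFamide
GPA2	FQHAWQTPGCHKVGHTRKISIPECVEFDITTNACRGYCE
Hyrg_1	YPEPAVIVDGRPNMIPDGYIQAPRFHYRGFQKPIPKYDWS	Hyrg
Hyrg_2	LPEAAVIVEGRPNRAPDDGYVQAAPPRFHYRGFQKFVPKYDWS	Hyrg
kinin_1	QSFSAWAamide	kinin
kinin_2	QAFSPWAamide	kinin
myosuppressin	pQDLDHVFLRFamide	myosuppressin
natalisin_1	EDSNLYSLVSDKEPSEINPFWVARamide	natalisin
natalisin_2	EGESNPYWIARamide	natalisin
NPF_1	ARTDNTAEVLQAMHEASLAGMLSSAEVPYPSRPNVFKSPVELRQYLDALNAYYAIAGRPRFamide	NPF
NPF_2	KPDPTQLAAMADALKYLQELDKYYSQVSRPSPRSAPGPASQIQALEKTLKFLQLQELGKLYSLRSRPRFamide	NPF
orcokinin_1	FDSFTTGFGHS	orcokinin
PDH_1	NSELINSLLGLPKVMNDAamide	PDH
PDH_2	NSGMINSLLGIPKVMTDAamide	PDH
proctolin	RYLPT	proctolin
pyrokinin_1	SPFSPRLamide	pyrokinin
pyrokinin_2	GDFAFSPRLamide	pyrokinin
RPCH	pQLNFSPGWamide	RPCH
RYamide	SSPSQSELPEIKIRSSRFIGGSRYamide	RYamide
sNPF_1	GPPSMRLRFamide	sNPF
sNPF_2	SEPSLRLRYamide	sNPF
sNPF_3	KDRTPALRLRFamide	sNPF
sNPF_4	APALRLRFamide	sNPF
SIFamide	GYRKPPFNGSIFamide	SIFamide
sulfakinin_1	pQFDEY(SO3H)GHMRFamide	sulfakinin
sulfakinin_2	AGGDYDDY(SO3H)GHLRFamide	sulfakinin
tachykinin	APSGFLGMRamide	tachykinin
vasopressin	CFITNCPPGamide	vasopressin
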