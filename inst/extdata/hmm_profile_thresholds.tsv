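accession	cutoff
CUST_G2LIKE	22.0
CUST_BELL	22.0
CUST_HDZIP	22.0
CUST_HRT	22.0
CUST_NFYB	20.0
CUST_NFYC	20.0
CUST_SAP	22.0
CUST_STAT	22.0
CUST_TRIHELIX	22.0
CUST_VOZ	22.0
CUST_WOX	22.0
CUST_VARL	22.0
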