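(((OTU1:0.00590733316,OTU2:0.00590733316):0.470602723,((((OTU3:0.04876874052,OTU4:0.04876874052):0.1640378102,OTU5:0.2128065507):0.104226851,(((OTU6:0.08719260289,(((OTU7:0.07205409226,(OTU8:0.0391306818,OTU9:0.0391306818):0.03292341047):0.00780410692,OTU10:0.07985819918):0.002433539058,OTU11:0.08229173824):0.004900864648):0.07574539003,(((OTU12:0.02513383109,(OTU13:0.006773402829,OTU14:0.006773402829):0.01836042827):0.004952403312,(OTU15:0.01251742057,(OTU16:6.198217948e-05,OTU17:6.198217948e-05):0.01245543839):0.01756881384):0.03567235417,(OTU18:0.02061035972,OTU19:0.02061035972):0.04514822885):0.09717940435):0.1184984273,(OTU20:0.1286812542,(OTU21:0.0232914003,OTU22:0.0232914003):0.1053898539):0.152755166):0.03559698152):0.05341850358,((((OTU23:0.01117721158,OTU24:0.01117721158):0.03155690719,OTU25:0.04273411878):0.06036197509,(OTU26:0.02102292656,OTU27:0.02102292656):0.0820731673):0.08780067855,OTU28:0.1908967724):0.1795551329):0.1060581508):0.9267818635,((((OTU29:0.03540657667,OTU30:0.03540657667):0.03988397878,((OTU31:0.002250926339,OTU32:0.002250926339):0.002436896497,OTU33:0.004687822836):0.07060273261):0.2065641321,(OTU34:0.04028148202,OTU35:0.04028148202):0.2415732055):0.07391248839,(OTU36:0.06945787605,(OTU37:0.05312413054,(OTU38:0.04652024501,(OTU39:0.02112078067,OTU40:0.02112078067):0.02539946434):0.006603885536):0.01633374551):0.2863092999):1.047524744);
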