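>p1
MRIEEVPFECVDTVGGCYDCGLIFACHEPLKNYKMDDFQFCVTVFQIIEEHLVQWSTNKMSIGAPQFKSM
LLAWTQQRGRMFPTTVCGGGYRCLNKICCMQCCLHLTTFDQQAFDPMYTYEPMTKTPTYATACISDFPNA
WFRGSLH
>p2
KKDVRRYSAGMKYPFMRCGTNSTMVCLEDRHTDYVKTGLKWKMMELTNGRKLIHQNWLFCDCQSEGYYMV
QAEPGNHNFVHPCDARYAKLHWVNLKWRQDYLCTVWQTL
>p3
FPVWWLSCEHAQYWNWGNWHWCGKMGFQLRAKHTCAMEDGFRYCEYKQQAYLAIYFGQEKISNLQMCSQD
TWKLPGAMPLPRTRIEGLYSNSWGHDKLHWPLQVPDLWCHYMYAGLKNPVRAMIPQF
>p4
GPDPLWSPPISGGILKLMAREHMLIDPYSIDKSMFHVHFYVHTDSIWVLRNDISLCIAPHMMPFCRTQFT
VTVHPCNDYIYQAQVCFLNDVVVRAIWIYCCYWMRVIACETNYWHKWHMNTCYHTEPWATECI
>p5
DPCEKMLQAAQYMKWFCKDNCSYTYIIWRGDAREKAMGYQKGNTMKVNWAMTTIMVAGCQFAVERHQLDH
FGFVKDDKPHLTCYTNGWLSALHCEYIRQTFTTRYGDQKNKQDEDHAFEINNNRKDDK
>p6
HNPTRRYDPYCFKVAEVFDLHQLLKHGYIFWYMTHLNEYDASFWTMAAVDFHFSPAWVLQLCSKHCRRDC
TDMFADQGSLIKDCGCSWFTNYEGCDVTVMIHYAWSIYVLLWPNIGHH
>p7
FAWMCVLGENGTQAMYWFDPWVYQCNQHRGNYMLTLWLKIWHEISMLYQHIFVACALKYTPGNWAMSQWA
IWSNPHARIGMHAYFFMTTTWPVLDTLAMPQPHIEQPYWQWRSDCGCLPLLCETVTLLLPIYFTKIWPAN
AGWPWFPQQY
>p8
NYIMQCQACLDCFRWNVVMYIKIDILLCMLDYCLQKMSRSWLCFWMVYMLFPLTDQLCFNRGAPKQNVHI
NNAWVCIARVQAGWMAAARVMALYKFGMFWGISTNLIIHQRRMLWVTR
>p9
WPYDLSPVAKMFQDFMQSFIGEFNVHPLSECNPARYNRSTTATLDTEMHLSHDSMFSPEWRIDKPFNELD
HGTYLYNQDVDRNRDYGLGMALDPFLSQAAMQAYDDTWTQAGGQTYYIKEHERHRSPTRAWISQWLRVCI
SFQHFNGTSFGFAYVLAGMN
>p10
DRQATDAPCPMGGHNAWPDIRFMPRQWDAPKTSTHNMNMFPFWLICPEEHPWPSLASKDANHRKCQNVNM
KDKAQWNQNYFEYFEYPPKKPPQKCKANVNRSNNIVMVPRHETEHFVPC
>p11
TLGCHQNIVDNWPSFFWINCSWNRAPCDAGKWMAFNGGQYPWCTRDDTEAISTNCVYLGFDMGKDYCLNY
QLYETRNYNCGDNWTSQETGRAHPFTTWGGWLRTNCCCEPFSWCFWLFPDSNEEETEVLILLCRDYYVWV
SPQRLF
>p12
CQHSEVGPAVNTKNHKNHQTPITCFEIHIRYYMINWDNKHCLGYLFYTYGCDNSMYKVHPLRNKQCAQPR
DWPTGGIWNKQGQCWKIPMQGAWIPMHNKRKMRMNQKMASMNMCERDKKYCGFTTKMDKKMCIYNTRSAD
PNRGTSDHCHQPIVHNYLWYTRVRQR
>p13
LLYGGKGHEAMLCEICNNSNRLWMHDIHLWWDAYKDCSHADEHFEGQQHCSETQPWFHMKMNECYSTVCD
KQQCYANPFAIIMDQCKHADAQ
>p14
AGNPFENEPMQVLCIHTQDCDDVGWVLSTQYCRRQLDWGIAEAPCHRYFFYANQPEHYPRVRICDRWQVP
TFQLIAWRMGQYLYVKFVWAAKYHMFNVYTVARINLNYRVHHCN
>p15
WWNQRNNICITARGFFPFQRFKWVNHMWLAKTWVENWKNLVHLGDQKMTNEIKHFHPVMSDTQRKEHDRH
YENKESEHINFQCLPHYPKPRGCQTYVRMMRGNLDQRMSYPYFGIKL
>p16
NACPKILPAPSLISTELKPWIIVQSSSPWEELFNEMNCTQGMALNPTIITTYCHPMSDHSERYAVNFLYL
YTTAQKWTCNGSYNYWKCGVGPSWMIYWDNVICYRSNPRLEFELRMPKQITHVYHDNGQERPI
>p17
YHCVMYMLCHRENFPVYYQALFQDMMFERSYEDARYWEVDPEVTNRWVEKYYPAAHEMNNVKEPQPQTRH
HVNCFMPENALSKINGGVAPIANQTAAYGNDQFCVPMMNATECM
>p18
ITIREWYTHRNFDSYYQRMMFMVWQHPEGSFKGNTLDGIDSQRNYGHISLDNMFYDKVNFQMDQSWA
>p19
HYCGFVHQEPAYIWYHLKHFRKDCTGWKWSMPKFDQMHTDVLQQQKFTARSVSRSSIKETYEMDTGMMLF
I
>p20
CFYCTLETYLATMSQSLDRHGNYLMDLKAQPPWWFDSHCHHHYLVEMQLRLCAMECCCYKRIAWKLHWVD
REQPVYTVMNCEWKEHLQKWMFKVIEMFDYFIRQVPDSDYKMLIYQIDSKKCAQDHIFGKTTFMSMTPIP
LQFSQN
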