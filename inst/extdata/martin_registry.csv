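martin_code,name,element,definition
M1,Maximum cranial length,vault,Maximum glabello-occipital length
M5,Skull base length,vault,Basion to nasion
M8,Maximum cranial breadth,vault,Widest measurement perpendicular to the medio-sagittal plane
M9,Least frontal breadth,vault,Distance between left and right frontotemporale
M11,Biauricular breadth,vault,Distance between left and right auriculare
M11b,Biradicular breadth,vault,Distance between left and right radiculare
M12,Biasterionic breadth,vault,Distance between left and right asterion
M17,Basi-bregmatic height,vault,Distance between basion and bregma
M40,Basion-prosthion length,face,Basion to prosthion
M45,Bizygomatic breadth,face,Distance between left and right zygion
M48,Upper facial height,face,Nasion to prosthion
M51,Orbital breadth,face,Maxillofrontale to ektokonchion
M52,Orbital height,face,Greatest height of orbit perpendicular to M51
M54,Nasal breadth,face,Maximal nasal breadth
M55,Nasal height,face,Nasion to nasospinale
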